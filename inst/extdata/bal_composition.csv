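subject,cell_type,flow_unscaled,flow_scaled,dnam_any,dnam_both
CF1,AlveolarMacrophage,2.4,5.2,0.7,0.5
CF1,Lymphocyte,2.5,5.5,1.6,1.8
CF1,Granulocyte,39.7,86.1,88.8,89.8
CF1,AEC,1.5,3.2,9.2,8.7
CF2,AlveolarMacrophage,46.1,55.7,29.9,33.7
CF2,Lymphocyte,7.4,8.9,19.7,16.3
CF2,Granulocyte,26.9,32.5,43.1,48.0
CF2,AEC,2.4,2.9,11.2,10.5
CF3,AlveolarMacrophage,42.5,64.6,37.3,39.3
CF3,Lymphocyte,5.3,8.0,22.3,20.7
CF3,Granulocyte,15.8,23.9,22.1,25.7
CF3,AEC,2.3,3.4,21.0,20.0
CF4,AlveolarMacrophage,50.2,72.5,66.6,68.6
CF4,Lymphocyte,5.0,7.2,11.6,10.0
CF4,Granulocyte,13.6,19.7,13.7,15.4
CF4,AEC,0.4,0.6,9.9,9.7
CF5,AlveolarMacrophage,31.3,63.2,50.7,52.8
CF5,Lymphocyte,3.6,7.2,11.0,9.5
CF5,Granulocyte,14.5,29.4,34.5,35.7
CF5,AEC,0.1,0.2,5.6,5.4
Control,AlveolarMacrophage,34.8,51.1,13.7,13.1
Control,Lymphocyte,13.9,20.5,17.8,16.7
Control,Granulocyte,14.6,21.5,58.7,61.7
Control,AEC,4.7,6.9,12.9,12.8
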