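# Small in-code fixtures shared across test files.

tiny_beta <- function(values, probes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- probes %||% sprintf("cg%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  m
}

ref_sheet <- function(ids, cell_types, pool_size = 1L) {
  data.frame(sample_id = ids, role = "reference", cell_type = cell_types,
             pool_size = pool_size, batch = "test",
             stringsAsFactors = FALSE)
}

# A small planted panel plus high-precision reference samples, reused by
# the selection / deconvolution tests.
planted_panel <- function(n_probes = 1500L, n_sig = 30L, delta = 0.5,
                          n_per_type = 3L, precision = 1e4, seed = 42L) {
  profiles <- generate_profiles(n_probes, n_signature_per_type = n_sig,
                                delta = delta, seed = seed)
  ref <- sample_individuals(profiles, n_per_type, precision,
                            seed = seed + 1L)
  list(profiles = profiles, beta = ref$beta, sheet = ref$sample_sheet)
}

# exhaustive simplex grid at the given resolution (default 1/100) for k = 4
simplex_grid <- function(k = 4L, steps = 100L) {
  stopifnot(k == 4L)
  g <- expand.grid(i = 0:steps, j = 0:steps, l = 0:steps)
  g <- g[g$i + g$j + g$l <= steps, ]
  cbind(g$i, g$j, g$l, steps - g$i - g$j - g$l) / steps
}

# grid-search oracle for the sum-to-one non-negative projection
grid_project <- function(y, X, grid = simplex_grid()) {
  Xty <- crossprod(X, y)
  XtX <- crossprod(X)
  obj <- -2 * (grid %*% Xty) + rowSums((grid %*% XtX) * grid)
  grid[which.min(obj), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
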