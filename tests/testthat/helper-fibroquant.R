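# Shared fixture builders; everything is generated in code.

# A phantom whose label map is a single class everywhere.
uniform_phantom <- function(class, h = 32L, w = 32L) {
  code <- match(class, TISSUE_CLASSES)
  fibroquant:::new_tissue_phantom(matrix(code, h, w), pixel_size_um = 0.5)
}

# A phantom from an explicit label matrix of class codes.
phantom_from_codes <- function(codes) {
  fibroquant:::new_tissue_phantom(codes, pixel_size_um = 0.5)
}

# Concentration maps directly from an n x 3 amount matrix (one "pixel" row).
conc_from_amounts <- function(amounts) {
  structure(list(amounts = amounts, shape = c(nrow(amounts), 1L)),
            class = "concentration_maps")
}

# point_labels straight from a data frame.
labels_from_df <- function(df) {
  structure(list(points = df), class = "point_labels")
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments
# (independent oracle; n must be small and |d| distinct).
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% rk)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}
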