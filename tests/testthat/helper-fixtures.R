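# shared fixtures, built in code

default_acq <- nf_acquisition()
default_design <- make_block_design(default_acq)

# a quiet ROI run for engine tests
quiet_truth <- function(amp = -0.5, thermal = 0.05, physio = 0, drift = 0,
                        frac = 0.5, seed = 1L) {
  nf_ground_truth(target_deactivation_pct = amp, thermal_sd = thermal,
                  physio_sd = physio, drift_amplitude = drift,
                  signal_fraction = frac, seed = seed)
}

# noiseless run built directly from the design matrix: every voxel is
# baseline * (1 + amp * convolved_regressor / 100)
make_noiseless_state <- function(amp, n_voxels = 5, acq = default_acq,
                                 design = default_design,
                                 baseline = seq(900, 1100,
                                                length.out = n_voxels)) {
  X <- build_design_matrix(design, acq$n_volumes, acq$tr_seconds)
  conv <- X[, "meditation"]
  Y <- sapply(seq_len(n_voxels),
              function(v) baseline[v] * (1 + amp * conv / 100))
  list(state = glm_state_from_data(Y, X), X = X, conv = conv, Y = Y,
       baseline = baseline)
}

# independent brute-force convolution of a boxcar with a kernel
brute_convolve <- function(box, h) {
  n <- length(box)
  out <- numeric(n)
  for (t in seq_len(n)) {
    for (k in seq_len(min(t, length(h)))) {
      out[t] <- out[t] + h[k] * box[t - k + 1]
    }
  }
  out
}

# independent exact rank-sum two-sided p by enumeration over assignments
enumerate_ranksum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  combs <- utils::combn(length(pooled), n1)
  Ws <- apply(combs, 2, function(idx) sum(r[idx]))
  EW <- n1 * (length(pooled) + 1) / 2
  Wobs <- sum(r[seq_len(n1)])
  mean(abs(Ws - EW) >= abs(Wobs - EW) - 1e-12)
}

# igraph-based flood fill: independent oracle for 6-connected components
igraph_label6 <- function(mask, dims) {
  idx <- which(mask)
  if (length(idx) == 0) return(integer(length(mask)))
  coord <- arrayInd(idx, dims)
  key <- function(m) (m[, 1] - 1) + dims[1] * ((m[, 2] - 1) +
                                                 dims[2] * (m[, 3] - 1))
  pos <- match(key(coord), key(coord))  # identity, for clarity
  edges <- NULL
  offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  lookup <- integer(prod(dims))
  lookup[idx] <- seq_along(idx)
  for (k in 1:3) {
    nb <- sweep(coord, 2, offs[k, ], `+`)
    ok <- nb[, 1] <= dims[1] & nb[, 2] <= dims[2] & nb[, 3] <= dims[3]
    nb_lin <- 1 + key(nb[ok, , drop = FALSE])
    has <- lookup[nb_lin] > 0
    edges <- rbind(edges,
                   cbind(which(ok)[has], lookup[nb_lin[has]]))
  }
  g <- igraph::graph_from_edgelist(edges[, 1:2, drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out <- integer(length(mask))
  out[idx] <- comp
  out
}

# canonical partition comparison: same clusters regardless of label order
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  all((a > 0) == (b > 0)) &&
    all(tapply(b[a > 0], a[a > 0], function(v) length(unique(v))) == 1) &&
    all(tapply(a[b > 0], b[b > 0], function(v) length(unique(v))) == 1)
}
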