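# Shared fixtures and independent oracles, built in code.

# a random rigid motion (rotation matrix + translation), seeded by caller
random_rigid <- function() {
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 20))
}

apply_rigid <- function(coords, rg) {
  sweep(coords %*% t(rg$R), 2, rg$t, "+")
}

# Brute-force plane-fit oracle: minimize the RMSD of point-plane distances
# directly over the plane orientation (spherical angles) and offset,
# independently of the SVD route.
bruteforce_planarity <- function(coords) {
  ctr <- colMeans(coords)
  centered <- sweep(coords, 2, ctr)
  obj <- function(par) {
    th <- par[1]; ph <- par[2]
    n <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    d <- centered %*% n - par[3]
    sqrt(mean(d^2))
  }
  best <- Inf
  for (th0 in seq(0.2, pi - 0.2, length.out = 4))
    for (ph0 in seq(0, 2 * pi * 3 / 4, length.out = 4)) {
      fit <- optim(c(th0, ph0, 0), obj,
                   control = list(maxit = 5000, reltol = 1e-15))
      fit <- optim(fit$par, obj, control = list(maxit = 5000, reltol = 1e-15))
      best <- min(best, fit$value)
    }
  best
}

# cached ideal stems (placement solve is ~0.5 s; reuse across tests)
.stem_cache <- new.env(parent = emptyenv())
ideal_stem <- function(n_quartets = 4, ...) {
  key <- paste(n_quartets, ..., sep = "_")
  if (is.null(.stem_cache[[key]]))
    .stem_cache[[key]] <- build_ideal_stem(stem_blueprint(n_quartets, ...))
  .stem_cache[[key]]
}

# build a minimal event_timeline by hand (for statistics tests)
fake_timeline <- function(types, terminus = NA, handedness = NA, frame = NULL) {
  n <- length(types)
  ev <- data.frame(type = types, frame = if (is.null(frame)) seq_len(n) * 100L
                   else frame,
                   time = seq_len(n) * 1.0, strand = rep(1L, n),
                   level = rep(NA_integer_, n),
                   edge = rep(NA_character_, n),
                   handedness = rep_len(handedness, n),
                   terminus = rep_len(as.integer(terminus), n),
                   slip = rep(NA_real_, n), residues = rep(NA_character_, n),
                   quartets_remaining_before = rep(NA_integer_, n),
                   stringsAsFactors = FALSE)
  structure(list(events = ev, persistence = 10), class = "event_timeline")
}
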