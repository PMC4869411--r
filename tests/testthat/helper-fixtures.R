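# Shared fixtures and independent oracles for the test suite.

# Independent dominant-eigenvalue oracle: shifted power iteration.
# The shift makes the iteration matrix primitive (the bare 3-stage annual
# matrix with d = 0 is imprimitive and cycles with period 3), so the
# iteration converges for every nonnegative matrix with a positive
# spectral radius.
power_lambda <- function(A, shift = 1, tol = 1e-14, maxit = 200000L) {
  B <- A + shift * diag(nrow(A))
  x <- rep(1, nrow(A))
  lam_old <- 0
  for (it in seq_len(maxit)) {
    y <- B %*% x
    lam <- max(abs(y))
    x <- as.vector(y) / lam
    if (abs(lam - lam_old) < tol * max(1, lam)) break
    lam_old <- lam
  }
  # Rayleigh quotient polishes the last digit
  as.numeric((t(x) %*% B %*% x) / sum(x * x)) - shift
}

# random feasible vital rates (d + g <= 1, all positive)
random_rates <- function() {
  g <- runif(1, 0.05, 0.95)
  d <- runif(1, 0, 1 - g)
  list(d = d, g = g, s = runif(1, 0.05, 0.95), f = runif(1, 5, 500))
}

# deterministic tiny census: one population, explicit fates
toy_census_df <- function() {
  data.frame(
    population_id = "wild_control_1",
    biotype = "wild",
    selection = "control",
    replicate = 1L,
    pan = c(1L, 1L, 2L, 2L),
    individual_id = paste0("ind", 1:4),
    germinated = c(TRUE, TRUE, TRUE, FALSE),
    flowered = c(TRUE, TRUE, FALSE, FALSE),
    fruit_count = c(10L, 7L, 0L, 0L),
    locule_counts = c("4;4;4;4;4;4;4;4;4;4", "3;5;4", "", ""),
    stringsAsFactors = FALSE)
}

# full-design census with per-population fate counts set directly:
# counts = data.frame(biotype, selection, replicate, n_germ, n_flower, f)
# every population gets n_seeds seeds; flowering plants all carry
# fruit/locule data giving exactly f seeds each (locule count 1).
design_census_df <- function(counts, n_seeds = 30L) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    ct <- counts[i, ]
    pop <- paste(ct$biotype, ct$selection, ct$replicate, sep = "_")
    germ <- seq_len(n_seeds) <= ct$n_germ
    flow <- seq_len(n_seeds) <= ct$n_flower
    data.frame(
      population_id = pop, biotype = ct$biotype, selection = ct$selection,
      replicate = ct$replicate,
      pan = rep_len(1:5, n_seeds),
      individual_id = paste0(pop, "_", seq_len(n_seeds)),
      germinated = germ, flowered = flow,
      fruit_count = ifelse(flow, as.integer(ct$f), 0L),
      locule_counts = ifelse(flow & ct$f > 0,
                             vapply(seq_len(n_seeds), function(j)
                               paste(rep("1", min(ct$f, 10)),
                                     collapse = ";"), character(1)),
                             ""),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# 18 labelled random feasible matrices covering the full design
random_design_matrices <- function(base = list(d = 0.1, g = 0.5, s = 0.7,
                                               f = 200),
                                   jitter = 0.15) {
  out <- list()
  for (b in c("wild", "hybrid")) for (s in c("early", "control", "long"))
    for (r in 1:3) {
      mult <- function() 1 + runif(1, -jitter, jitter)
      rates <- list(d = min(base$d * mult(), 1 - base$g * (1 + jitter)),
                    g = base$g * mult(), s = base$s * mult(),
                    f = base$f * mult())
      nm <- paste(b, s, r, sep = "_")
      out[[nm]] <- build_matrix(rates, labels = list(
        population_id = nm, biotype = b, selection = s, replicate = r))
    }
  out
}

# uniform design: every population shares the same matrix
constant_design_matrices <- function(rates = list(d = 0.1, g = 0.5,
                                                  s = 0.7, f = 200)) {
  out <- list()
  for (b in c("wild", "hybrid")) for (s in c("early", "control", "long"))
    for (r in 1:3) {
      nm <- paste(b, s, r, sep = "_")
      out[[nm]] <- build_matrix(rates, labels = list(
        population_id = nm, biotype = b, selection = s, replicate = r))
    }
  out
}

# per-population vital-rate table from a deterministic design spec,
# bypassing census sampling (for the statistics tests)
rates_table <- function(g, s, f, lambda = NULL) {
  grid <- expand.grid(replicate = 1:3,
                      selection = c("early", "control", "long"),
                      biotype = c("wild", "hybrid"),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("biotype", "selection", "replicate")]
  grid$g <- g; grid$s <- s; grid$f <- f
  if (!is.null(lambda)) grid$lambda <- lambda
  grid
}
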