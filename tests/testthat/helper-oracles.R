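# Independent oracles and small fixture builders shared across tests.
# Oracles are written naively (loops, explicit enumeration) on purpose so
# that they share no code path with the implementation they check.

# Truth-table evaluation of the diagnostic rule for one subject.
# x: named vector of 12 values in {0, 1, NA}, names = criterion ids.
oracle_diagnosis <- function(x, model) {
  hit <- function(id) isTRUE(x[[id]] == 1)
  ni <- FALSE
  for (id in c("global_intellectual", "executive_function", "learning",
               "memory", "visual_spatial")) if (hit(id)) ni <- TRUE
  sr <- FALSE
  for (id in c("mood_behavior", "attention", "impulse_control"))
    if (hit(id)) sr <- TRUE
  af <- if (model == "AF1") {
    hit("communication") || hit("social") || hit("daily_living")
  } else {
    (hit("communication") || hit("social")) &&
      (hit("daily_living") || hit("motor"))
  }
  c(ni = ni, sr = sr, af = af, ndpae = ni && sr && af)
}

# O(n^2) pairwise Mann-Whitney AUC.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  s <- 0
  for (p in pos) for (q in neg) {
    if (p > q) s <- s + 1 else if (p == q) s <- s + 0.5
  }
  s / (length(pos) * length(neg))
}

# Expected-counts Pearson chi-square, sum (O - E)^2 / E.
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Wrap a plain 0/1/NA matrix as an ndpae_cmat for the diagnosis engine.
as_cmat <- function(m, group = rep("AE", nrow(m)), tau = 1) {
  colnames(m) <- ndpae_criteria()$criterion
  rownames(m) <- sprintf("S%03d", seq_len(nrow(m)))
  structure(m, class = "ndpae_cmat", tau = tau, iq_tau = tau,
            group = factor(group, levels = c("AE", "CON")),
            cohort_n = nrow(m))
}

# A tiny hand-written cohort on the simulated battery.
tiny_cohort <- function() {
  reg <- synth_registry()
  df <- data.frame(subject_id = c("a", "b", "c"),
                   group = c("AE", "AE", "CON"),
                   age = c(8, 12, 10),
                   sex = c("female", "male", "male"),
                   stringsAsFactors = FALSE)
  for (m in reg$measure_id) df[[m]] <- c(100, 100, 100)
  # put every measure at its scale midpoint (z = 0)
  df[reg$measure_id[reg$scale == "t_50_10"]] <- 50
  df[reg$measure_id[reg$scale == "scaled_10_3"]] <- 10
  df
}

# Items from a 3-factor model with block loadings and factor correlation
# phi_off; 12 items, 4 per factor, unit marginal variance.
make_factor_items <- function(n, phi_off, loading = 0.8, seed = 42) {
  set.seed(seed)
  Phi <- matrix(phi_off, 3, 3); diag(Phi) <- 1
  L <- matrix(0, 12, 3)
  L[1:4, 1] <- L[5:8, 2] <- L[9:12, 3] <- loading
  F <- matrix(rnorm(n * 3), n, 3) %*% chol(Phi)
  F %*% t(L) + sqrt(1 - loading^2) * matrix(rnorm(n * 12), n, 12)
}
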