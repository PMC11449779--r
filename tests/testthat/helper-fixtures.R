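# Shared fixtures: small generator configs and hand-built family datasets.

small_cfg <- function(n_sib = 2000L, n_mz = 500L, n_dz = 500L, seed = 1L, ...) {
  generator_config(n_sib_pairs = n_sib, n_mz_pairs = n_mz, n_dz_pairs = n_dz,
                   seed = seed, ...)
}

# Correlated standard-normal pairs (for constructed twin inputs).
rbvn_pairs <- function(n, rho) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cbind(z1, z2)
}

# Hand-built family dataset: one row per person, sum scores realized through
# dx_ columns (score k = first k of `p` conditions diagnosed).
make_pairs_dataset <- function(older_scores, younger_scores,
                               relationship = "full_sibling",
                               ages = NULL, p = NULL) {
  n <- length(older_scores)
  stopifnot(length(younger_scores) == n)
  p <- p %||% max(older_scores, younger_scores, 1)
  score_to_dx <- function(k) {
    m <- matrix(0L, length(k), p)
    for (i in seq_along(k)) if (k[i] > 0) m[i, seq_len(k[i])] <- 1L
    m
  }
  roles <- if (relationship == "full_sibling") c("older_sib", "younger_sib")
           else c("twin1", "twin2")
  dx <- matrix(0L, 2 * n, p)
  dx[seq(1, 2 * n, 2), ] <- score_to_dx(older_scores)
  dx[seq(2, 2 * n, 2), ] <- score_to_dx(younger_scores)
  colnames(dx) <- paste0("dx_c", seq_len(p))
  ages <- ages %||% rep(25, 2 * n)
  d <- data.frame(family_id = rep(seq_len(n), each = 2),
                  person_id = seq_len(2 * n),
                  role = rep(roles, n),
                  relationship = relationship,
                  age = ages, stringsAsFactors = FALSE)
  d <- cbind(d, as.data.frame(dx))
  d$id_severity <- "none"
  class(d) <- c("family_dataset", "data.frame")
  d
}

# Twin dataset carrying an arbitrary numeric score column (liability-scale
# tests bypass the binary layer entirely).
make_twin_scores <- function(mz_pairs, dz_pairs, score_name = "score") {
  n_mz <- nrow(mz_pairs); n_dz <- nrow(dz_pairs)
  n <- n_mz + n_dz
  d <- data.frame(
    family_id = rep(seq_len(n), each = 2),
    person_id = seq_len(2 * n),
    role = rep(c("twin1", "twin2"), n),
    relationship = rep(c(rep("MZ", n_mz), rep("DZ", n_dz)), each = 2),
    age = 25,
    dx_dummy = 0L,
    id_severity = "none", stringsAsFactors = FALSE)
  d[[score_name]] <- c(t(rbind(mz_pairs, dz_pairs)))
  class(d) <- c("family_dataset", "data.frame")
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
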