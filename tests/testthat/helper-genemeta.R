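# Shared fixtures and small independent oracles.

mdm2 <- mdm2_studies()

# plain data.frame view for content comparisons (drops provenance/rownames)
plain <- function(d) {
  d <- as.data.frame(d)
  attr(d, "provenance") <- NULL
  rownames(d) <- NULL
  d
}

# random strictly-positive 2x2 table
random_table <- function(max_cell = 200) {
  cells <- sample.int(max_cell, 4, replace = TRUE)
  structure(list(a = cells[1], b = cells[2], c = cells[3], d = cells[4],
                 cc_applied = FALSE, model = "dominant", study_id = "rnd"),
            class = "gm_2x2")
}

# random per-study estimates data.frame
random_estimates <- function(k) {
  data.frame(study_id = paste0("s", seq_len(k)),
             log_or = stats::rnorm(k, 0, 0.5),
             se = stats::runif(k, 0.05, 0.8),
             stringsAsFactors = FALSE)
}

# closed-form simple linear regression of y on x: intercept, its SE, t
ols_oracle <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  slope <- sum((x - xb) * (y - yb)) / sxx
  int <- yb - slope * xb
  res <- y - int - slope * x
  s2 <- sum(res^2) / (n - 2)
  se_int <- sqrt(s2 * (1 / n + xb^2 / sxx))
  list(intercept = int, slope = slope, se_intercept = se_int,
       t = int / se_int)
}

# direct evaluation of the Mantel-Haenszel pooled OR definition
mh_oracle <- function(tabs) {
  num <- sum(vapply(tabs, function(t)
    t$a * t$d / (t$a + t$b + t$c + t$d), numeric(1)))
  den <- sum(vapply(tabs, function(t)
    t$b * t$c / (t$a + t$b + t$c + t$d), numeric(1)))
  num / den
}

# exhaustive-enumeration exact HWE oracle: factorial-based probabilities of
# every heterozygote count compatible with the observed allele counts
hwe_exact_oracle <- function(gg, gt, tt) {
  n <- gg + gt + tt
  n_g <- 2 * gg + gt
  n_t <- 2 * n - n_g
  hets <- seq(n_g %% 2, min(n_g, n_t), by = 2)
  pr <- vapply(hets, function(h) {
    factorial(n) / (factorial((n_g - h) / 2) * factorial(h) *
                      factorial((n_t - h) / 2)) * 2^h
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(gt, hets)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}
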