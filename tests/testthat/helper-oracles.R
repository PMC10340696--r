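# Independent oracles and small fixture builders shared across tests.

# Brute-force sequential ANOVA: fit each nested sub-model by least squares
# on explicit dummy matrices and difference residual sums of squares.
# Independent of the fitting path used by fit_anova().
brute_force_anova <- function(d, full = TRUE) {
  d$genotype <- factor(d$genotype)
  d$year <- factor(d$year)
  dummies <- function(f) {
    f <- factor(f)
    m <- outer(f, levels(f), `==`) * 1
    colnames(m) <- levels(f)
    m
  }
  blocks <- list(year = dummies(d$year))
  if (full) {
    blocks$rep_within_year <- dummies(paste(d$year, d$rep))
    blocks$genotype <- dummies(d$genotype)
    blocks$genotype_x_year <- dummies(paste(d$genotype, d$year))
  } else {
    blocks$genotype <- dummies(d$genotype)
  }
  rss_rank <- function(X) {
    q <- qr(X)
    res <- qr.resid(q, d$value)
    c(rss = sum(res^2), rank = q$rank)
  }
  X <- matrix(1, nrow(d), 1)
  prev <- rss_rank(X)
  out <- data.frame(term = character(), df = integer(), ss = numeric(),
                    stringsAsFactors = FALSE)
  for (nm in names(blocks)) {
    X <- cbind(X, blocks[[nm]])
    cur <- rss_rank(X)
    out <- rbind(out, data.frame(term = nm, df = cur["rank"] - prev["rank"],
                                 ss = prev["rss"] - cur["rss"]))
    prev <- cur
  }
  out <- rbind(out, data.frame(term = "error",
                               df = nrow(d) - prev["rank"],
                               ss = prev["rss"]))
  out$ms <- out$ss / out$df
  rownames(out) <- NULL
  out
}

# Balanced random phenotype table for one trait.
random_balanced_pheno <- function(g, y, r, trait = "t", sd = 1) {
  idx <- expand.grid(genotype = sprintf("G%02d", seq_len(g)),
                     year = sprintf("Y%d", seq_len(y)),
                     rep = sprintf("R%d", seq_len(r)),
                     stringsAsFactors = FALSE)
  idx$trait <- trait
  idx$value <- rnorm(nrow(idx), 10, sd)
  idx
}

# Benjamini-Hochberg from the step-up definition:
# adj(i) = min_{j: p(j) >= p(i)} n * p(j) / rank(j), capped at 1.
bh_brute_force <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- pmin(n * ranked / seq_len(n), 1)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Small SE-HPLC fraction-area table.
toy_fraction_areas <- function(e, u, sample = "s1") {
  d <- data.frame(sample = sample)
  for (k in seq_along(e)) d[[paste0("E_F", k)]] <- e[k]
  for (k in seq_along(u)) d[[paste0("U_F", k)]] <- u[k]
  d
}
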