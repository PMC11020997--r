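# shared fixtures and independent oracles

# minimal effect-pair data.frame (already harmonized)
make_hdata <- function(g, G, seg = 0.01, seG = 0.02, ids = NULL) {
  data.frame(variant_id = ids %||% paste0("rs", seq_along(g)),
             beta_exposure = g, se_exposure = rep_len(seg, length(g)),
             beta_outcome = G, se_outcome = rep_len(seG, length(g)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# summary-record data.frame builder for harmonization tests
make_records <- function(ids, ea, oa, beta, se, p, eaf = NA_real_) {
  data.frame(variant_id = ids, chrom = NA_character_, pos = NA_integer_,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pvalue = p, n = NA_real_,
             stringsAsFactors = FALSE)
}

# oracle: weighted least squares through the normal equations
wls_oracle <- function(X, y, w) {
  Xw <- X * sqrt(w); yw <- y * sqrt(w)
  solve(crossprod(Xw), crossprod(Xw, yw))[, 1]
}

# oracle: dense-grid argmax of the smoothed ratio density
grid_mode_oracle <- function(b, w, h, n_grid = 200001) {
  xs <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = n_grid)
  dens <- vapply(xs, function(x) sum(w * dnorm(x, b, h)), numeric(1))
  xs[which.max(dens)]
}

# oracle: MR-BMA posterior probabilities by Gauss-Legendre quadrature over
# the effect priors (K <= 3), on already-standardized inputs
bma_quadrature_oracle <- function(X, y, pi_ = 0.1, s2 = 0.25,
                                  n_nodes = 64) {
  K <- ncol(X)
  gl <- pracma::gaussLegendre(n_nodes, -8 * sqrt(s2), 8 * sqrt(s2))
  lik_int <- function(S) {
    m <- length(S)
    grid <- do.call(expand.grid, rep(list(seq_len(n_nodes)), m))
    tot <- 0
    for (r in seq_len(nrow(grid))) {
      idx <- as.integer(grid[r, ]); th <- gl$x[idx]
      mu <- as.vector(X[, S, drop = FALSE] %*% th)
      tot <- tot + prod(gl$w[idx]) *
        exp(sum(dnorm(y, mu, 1, log = TRUE)) +
              sum(dnorm(th, 0, sqrt(s2), log = TRUE)))
    }
    tot
  }
  subsets <- unlist(lapply(seq_len(K), function(m)
    utils::combn(K, m, simplify = FALSE)), recursive = FALSE)
  ints <- c(exp(sum(dnorm(y, 0, 1, log = TRUE))),
            vapply(subsets, lik_int, numeric(1)))
  priors <- c((1 - pi_)^K, vapply(subsets, function(S)
    pi_^length(S) * (1 - pi_)^(K - length(S)), numeric(1)))
  p <- ints * priors
  p / sum(p)
}

# write a small gwas table to a temp file, returning the path
write_gwas_fixture <- function(lines, gz = FALSE) {
  f <- tempfile(fileext = if (gz) ".tsv.gz" else ".tsv")
  con <- if (gz) gzfile(f, "w") else file(f, "w")
  writeLines(lines, con)
  close(con)
  f
}

std_map <- c(variant_id = "SNP", effect_allele = "EA", other_allele = "OA",
             eaf = "EAF", beta = "BETA", se = "SE", pvalue = "P", n = "N")
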