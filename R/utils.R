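# Internal helpers shared across modules.

# Stable 31-bit hash of a character string (polynomial rolling hash).
# Used to fan a single pipeline seed out into per-stage sub-seeds so that
# enabling or disabling one stage never perturbs another stage's stream.
stableHash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 2147483647 + stableHash(stage)) %% 2147483647)
}

assertSeed <- function(seed) {
  if (missing(seed) || is.null(seed) || length(seed) != 1L || is.na(seed) ||
      !is.numeric(seed))
    stop("a single integer 'seed' is mandatory for every generator")
  as.integer(seed)
}

assertFraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("'", name, "' must be a single value in [0, 1]")
  x
}

assertNonNegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop("'", name, "' must be a single non-negative value")
  x
}

# Lognormal multiplicative noise with a given coefficient of variation:
# E[factor] = 1, CV(factor) = cv.
rlnormCV <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# Beta-binomial draws with mean prob and intra-class correlation rho.
# rho = 0 degenerates to the plain binomial.
rbetabinom <- function(n, size, prob, rho) {
  if (rho == 0) return(stats::rbinom(n, size, prob))
  if (rho < 0 || rho >= 1) stop("overdispersion 'rho' must be in [0, 1)")
  p <- ifelse(prob <= 0, 0,
       ifelse(prob >= 1, 1,
              stats::rbeta(n, prob * (1 - rho) / rho,
                           (1 - prob) * (1 - rho) / rho)))
  stats::rbinom(n, size, p)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
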