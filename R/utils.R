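# Internal helpers shared across modules.

DOMAINS <- c("mobility", "iadl", "adl")
TRANSITIONS <- c("onset", "recover", "die_nd", "die_dis")
SEXES <- c("female", "male")
STATES <- c("ND", "STD", "NDH", "LTD", "DEAD")

# thresholds: number of item difficulties that constitutes domain disability
DOMAIN_THRESHOLDS <- c(mobility = 4L, iadl = 1L, adl = 1L)

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x, eps = 1e-9) pmin(pmax(x, eps), 1 - eps)

# Deterministic child seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647)
}

# Row-wise ranks of an n x 5 matrix of distinct uniforms (1 = smallest),
# without apply(): used to place item difficulties at random positions.
rank5 <- function(u) {
  r <- matrix(1L, nrow(u), ncol(u))
  for (i in seq_len(ncol(u))) {
    for (j in seq_len(ncol(u))) {
      if (i != j) r[, i] <- r[, i] + (u[, j] < u[, i])
    }
  }
  r
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
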