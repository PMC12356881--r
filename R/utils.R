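# internal numerics shared across modules

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cheap content fingerprint for provenance fields (not cryptographic)
fingerprint <- function(x) {
  v <- as.numeric(x)
  sprintf("%dx%s", length(v), format(sum(v * seq_along(v)) + sum(v^2), digits = 17))
}

stop_input <- function(...) stop(..., call. = FALSE)

# vectorised per-SNP marginal ordinary least squares of y on each column of G.
# Returns beta, se, pval, and drops nothing: zero-variance columns yield NA.
marginal_ols <- function(G, y) {
  n <- length(y)
  stopifnot(nrow(G) == n, n > 2)
  gc <- sweep(G, 2, colMeans(G))
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  sxy <- drop(crossprod(gc, yc))
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  syy <- sum(yc^2)
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / ((n - 2) * sxx))
  tstat <- beta / se
  pval <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  data.frame(beta = beta, se = se, pval = pval, row.names = NULL)
}
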