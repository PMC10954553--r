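#' @useDynLib cnddtools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats as.formula coef lm median model.matrix optim p.adjust
#'   pnorm prcomp predict qlogis qnorm quantile rbinom rlnorm rnorm rpois
#'   runif sd setNames terms var vcov cor.test logLik
#' @importFrom utils head modifyList
NULL

# Hierarchical seed splitting: derive child seeds from a parent seed and a
# stream label so that adding sites/censuses never perturbs earlier streams.
# Kept below 2^31 - 1 (R integers are 32-bit).
split_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  # FNV-1a style hash folded to a positive 31-bit integer
  h <- 2166136261 %% 2147483647
  for (ch in utf8ToInt(labels)) {
    h <- bitwXor(as.integer(h), as.integer(ch))
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(max(1, round(h)))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Basal area of a stem
#'
#' Cross-sectional area at breast height, `pi * (dbh / 2)^2`, in cm^2.
#'
#' @param dbh Diameter at breast height in cm.
#' @return Basal area in cm^2.
#' @export
basal_area <- function(dbh) pi * (dbh / 2)^2

# cloglog inverse link with offset log(dt): p = 1 - exp(-exp(eta + log dt))
cloglog_inv <- function(eta, dt = 1) -expm1(-exp(eta + log(dt)))

# rank-based AUC (Mann-Whitney); returns NA when one class is absent
auc_rank <- function(y, p) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
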