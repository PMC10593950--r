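#' @importFrom stats rnorm runif rbinom sd cor qnorm pnorm pt plogis lm glm
#'   binomial coef vcov prcomp complete.cases p.adjust uniroot resid model.matrix
#'   quantile median
#' @importFrom utils head modifyList
#' @import data.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stage-level child seeds: one user-facing seed fans out to per-component
# seeds so that, e.g., regenerating phenotypes does not disturb the genotype
# stream. Offsets are fixed per stage name; result kept inside 32-bit range.
.stage_offsets <- c(
  genotypes  = 101L,
  annotation = 211L,
  sumstats   = 307L,
  phenotypes = 401L,
  permutation = 503L,
  pipeline   = 601L
)

child_seed <- function(seed, stage) {
  stopifnot(stage %in% names(.stage_offsets))
  (as.integer(seed) %% 1000000L) * 1009L + .stage_offsets[[stage]]
}

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

zscore <- function(x) {
  s <- sd(x)
  .assert(is.finite(s) && s > 0, "cannot standardize a constant vector")
  (x - mean(x)) / s
}
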