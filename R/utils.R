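#' @useDynLib cryoflux, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov cmdscale kruskal.test p.adjust pnorm quantile rnorm
#'   runif sd setNames shapiro.test var wilcox.test TukeyHSD rbinom rgamma
#'   rmultinom
#' @importFrom utils read.csv read.delim write.csv
NULL

# Derive a deterministic per-component seed from a master seed. Counter-based
# so adding a new component never perturbs the streams of existing ones.
# Keeps the result in [0, 2^31 - 2] (valid R integer seed).
substream_seed <- function(seed, id) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(id)) * seq_along(utf8ToInt(as.character(id))))
  as.integer((abs(seed) * 69069 + h * 2654435) %% 2147483647)
}

# Evaluate expr with a local RNG state seeded from `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
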