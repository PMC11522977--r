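#' @useDynLib cuticlenet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats anova aov as.dist cor cutree hclust lm median mad
#'   p.adjust phyper prcomp ptukey quantile rnorm runif sd setNames var
#' @importFrom utils head modifyList
NULL

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. All stochastic stages in the package go through this, so a single
# integer seed pins down the whole pipeline.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a deterministic child seed from a parent seed and a stage label.
# Keeps every stage on its own substream while the user supplies one integer.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587L) + 1L
}

cn_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(format(Sys.time(), "%H:%M:%S "), sprintf(...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
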