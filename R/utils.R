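#' @import methods
#' @importFrom stats rnorm rnbinom runif var cor sd quantile rmultinom
#' @importFrom utils write.table read.table head packageVersion
NULL

# Run `expr` under `seed` without disturbing the caller's RNG stream.
withLocalSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Integer apportionment of n among categories with probabilities p
# (largest-remainder / Hamilton rounding; ties by name order).
largestRemainder <- function(p, n) {
  stopifnot(abs(sum(p) - 1) < 1e-6, n >= 0)
  exact <- p * n
  base <- floor(exact)
  short <- n - sum(base)
  if (short > 0) {
    rem <- exact - base
    ord <- order(-rem, names(p))
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1L
  }
  stats::setNames(as.integer(base), names(p))
}

# Canonical JSON of an R object (names sorted recursively) -> md5 hash.
canonicalize <- function(x) {
  if (is.list(x) && !is.null(names(x))) {
    x <- x[order(names(x))]
    lapply(x, canonicalize)
  } else if (is.list(x)) {
    lapply(x, canonicalize)
  } else x
}

hashObject <- function(x) {
  json <- jsonlite::toJSON(canonicalize(x), auto_unbox = TRUE, digits = NA,
                           null = "null", force = TRUE)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(json, tf)
  unname(tools::md5sum(tf))
}

# Stage order bookkeeping: stages live in metadata(sce)$stages.
stageLevels <- function(sce, stages = NULL) {
  if (!is.null(stages)) return(stages)
  st <- S4Vectors::metadata(sce)$stages
  if (is.null(st)) st <- unique(as.character(sce$stage))
  st
}

transitionLabel <- function(from, to) paste0(from, "->", to)

majorTypeOf <- function(subtype) {
  ifelse(grepl("^CM", subtype), "CM", as.character(subtype))
}

# Column-wise average ranks of a genes x cells matrix (ties -> average).
rankColumns <- function(m) {
  apply(m, 2L, rank, ties.method = "average")
}
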