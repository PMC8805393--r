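#' Canonical anti-dementia drug order
#'
#' The four drugs licensed for cognitive symptoms in dementia, in the fixed
#' canonical order used by every 4-vector in the package (effect vectors,
#' one-hot encodings, predicted-score vectors). The order is the tie-break
#' order: whenever an argmax over drugs is tied, the earliest drug in this
#' vector wins.
#'
#' @return Character vector
#'   `c("donepezil", "galantamine", "rivastigmine", "memantine")`.
#' @export
dementia_drugs <- function() {
  c("donepezil", "galantamine", "rivastigmine", "memantine")
}

#' Acetylcholinesterase inhibitors
#'
#' The AChEI subset of [dementia_drugs()], used for AChEI-only
#' recommendation mode (memantine excluded).
#'
#' @return Character vector of the three AChEIs in canonical order.
#' @export
achei_drugs <- function() {
  c("donepezil", "galantamine", "rivastigmine")
}

# run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# argmax with ties broken by position (canonical order)
argmax_first <- function(x) which.max(x)
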