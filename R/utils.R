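.BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Evaluates `code` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded internals never perturb user simulations.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ACGT -> 1:4, anything else (N, gaps) -> NA
encode_seq <- function(s) {
  if (length(s) == 1L && nchar(s) != 1L) s <- strsplit(s, "", fixed = TRUE)[[1]]
  match(toupper(s), .BASES)
}

decode_seq <- function(codes) paste(.BASES[codes], collapse = "")

revcomp <- function(s) {
  stopifnot(is.character(s))
  vapply(s, function(x) {
    x <- chartr("ACGTacgtN", "TGCAtgcaN", x)
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

stop_fmt <- function(class, fmt, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
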