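# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards.  All simulators route through this so a
# call never perturbs (nor depends on) global RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Substitute each base independently with probability `rate`; substitutions
# always change the base.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(x)) < rate)
  if (length(hit)) {
    x[hit] <- vapply(x[hit], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  }
  paste(x, collapse = "")
}

revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(seq, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
         }, "", USE.NAMES = FALSE))
}

# All k-mers of a sequence as a character vector (character-level; used for
# spectra and sketch identity where Biostrings machinery is heavier than
# needed).
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

new_sim_truth <- function(generator_name, seed, planted_params) {
  structure(
    list(generator_name = generator_name, seed = as.integer(seed),
         planted_params = planted_params),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulation truth <", x$generator_name, "> seed ", x$seed, "\n", sep = "")
  nm <- names(x$planted_params)
  for (i in seq_along(nm)) {
    v <- x$planted_params[[i]]
    cat("  ", nm[i], ": ",
        if (length(v) > 6L) paste0("[", length(v), " values]")
        else paste(signif(unlist(v), 6), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Write a simulation truth object as a JSON sidecar
#'
#' Conventionally saved next to the dataset it describes as
#' `<name>.truth.json`, so downstream recovery tests can reload the
#' planted parameters without the generating session.
#'
#' @param truth A `sim_truth` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a simulation truth sidecar written by [write_truth_json()]
#'
#' @param path JSON path.
#' @return A `sim_truth` object.
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_sim_truth(x$generator_name, x$seed, x$planted_params)
}

stopifnot_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single number in [%g, %g]", name, lo, hi),
         call. = FALSE)
  }
}
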