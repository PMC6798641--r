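#' Fold an RNA sequence by Nussinov base-pair maximisation
#'
#' A dependency-free secondary-structure folder: maximises the number of
#' nested base pairs (AU/UA, GC/CG and the GU/UG wobble) subject to a
#' minimum hairpin-loop size, and returns one optimal structure by a
#' deterministic traceback that prefers pairing the leftmost 5' index.
#' This is a combinatorial surrogate for a thermodynamic
#' minimum-free-energy folder such as `RNAfold` (see [fold_external()]):
#' adequate for synthetic hairpins and tests, coarser on real sequences.
#'
#' @param seq RNA string over `{A,C,G,U}` (sentinel `N` never pairs).
#' @param min_loop Minimum number of unpaired bases enclosed by a pair
#'   (default 3, the standard steric constraint).
#' @return A list of class `fold_result` with elements `structure`
#'   (dot-bracket string), `pair_count` and `source = "nussinov"`.
#' @examples
#' fold_nussinov("GGGAAACCC")
#' @export
fold_nussinov <- function(seq, min_loop = 3) {
  seq <- toupper(gsub("T", "U", seq, fixed = TRUE))
  if (!nzchar(seq)) abort("empty sequence", class = "premir_format_error")
  if (min_loop < 0) abort("min_loop must be >= 0")
  res <- nussinov_fold_cpp(seq, as.integer(min_loop))
  structure(list(structure = res$structure, pair_count = res$pair_count,
                 energy = NA_real_, source = "nussinov"),
            class = "fold_result")
}

#' Fold an RNA sequence with an external MFE folder
#'
#' Runs an RNAfold-compatible binary (sequence on stdin, dot-bracket plus
#' free energy on stdout) and parses its output. This is the preferred
#' route for real data; the built-in [fold_nussinov()] is the fallback when
#' no binary is available.
#'
#' @param seq RNA string.
#' @param binary Name or path of the folding binary (default `"RNAfold"`).
#' @return A `fold_result` list with `source = "external_mfe"` and the
#'   reported free energy in `energy`.
#' @export
fold_external <- function(seq, binary = "RNAfold") {
  path <- Sys.which(binary)
  if (!nzchar(path)) {
    abort(paste0("external folder '", binary, "' not found on PATH; ",
                 "use fold_nussinov() instead"),
      class = "premir_environment_error")
  }
  out <- suppressWarnings(
    system2(path, args = "--noPS", input = seq, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    abort(paste0("external folder exited with status ", status, "; ",
                 "use fold_nussinov() instead"),
      class = "premir_environment_error")
  }
  strline <- trimws(out[length(out)])
  m <- regmatches(strline, regexec("^([().]+)\\s*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", strline))[[1]]
  if (length(m) == 0) {
    abort(paste0("cannot parse folder output: ", strline),
      class = "premir_format_error")
  }
  db <- m[2]
  if (nchar(db) != nchar(seq)) {
    abort("folder returned a structure of the wrong length",
      class = "premir_format_error")
  }
  structure(list(structure = db, pair_count = sum(strsplit(db, "")[[1]] == "("),
                 energy = as.numeric(m[3]), source = "external_mfe"),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$structure, "\n", sep = "")
  cat(x$pair_count, "pairs (", x$source, ")\n")
  invisible(x)
}

#' Validate a dot-bracket structure and list its base pairs
#'
#' Performs a stack scan of a dot-bracket string: every `)` must close an
#' earlier `(`, and no brackets may remain open at the end.
#'
#' @param db Dot-bracket string over `{(, ., )}`.
#' @return A tibble with 1-based columns `i` (opening) and `j` (closing
#'   position), one row per base pair; zero rows for an unpaired structure.
#' @examples
#' validate_structure("(((...)))")
#' @export
validate_structure <- function(db) {
  chars <- strsplit(db, "")[[1]]
  bad <- which(!chars %in% c("(", ".", ")"))
  if (length(bad) > 0) {
    abort(paste0("invalid structure character '", chars[bad[1]],
                 "' at position ", bad[1]),
      class = "premir_format_error")
  }
  stack <- integer(0)
  pairs_i <- integer(0)
  pairs_j <- integer(0)
  for (pos in seq_along(chars)) {
    if (chars[pos] == "(") {
      stack <- c(stack, pos)
    } else if (chars[pos] == ")") {
      if (length(stack) == 0) {
        abort(paste0("unmatched ')' at position ", pos),
          class = "premir_format_error")
      }
      pairs_i <- c(pairs_i, stack[length(stack)])
      pairs_j <- c(pairs_j, pos)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0) {
    abort(paste0("unmatched '(' at position ", stack[length(stack)],
                 " (end of string reached)"),
      class = "premir_format_error")
  }
  ord <- order(pairs_i)
  tibble::tibble(i = pairs_i[ord], j = pairs_j[ord])
}

#' Attach secondary structures to every record of a dataset
#'
#' Fills the `structure` column using the built-in Nussinov folder or an
#' external MFE binary.
#'
#' @param ds A hairpin dataset tibble.
#' @param method `"nussinov"` (default) or `"external"`.
#' @param min_loop Minimum hairpin-loop size for the Nussinov folder.
#' @param binary External binary name for `method = "external"`.
#' @param overwrite Refold records that already carry a structure?
#' @return The dataset with `structure` (and, for external folding,
#'   `energy`) filled in.
#' @export
fold_dataset <- function(ds, method = c("nussinov", "external"),
                         min_loop = 3, binary = "RNAfold",
                         overwrite = FALSE) {
  method <- match.arg(method)
  ds <- validate_dataset(ds)
  todo <- if (overwrite) seq_len(nrow(ds)) else which(is.na(ds$structure))
  for (i in todo) {
    fr <- if (method == "nussinov") {
      fold_nussinov(ds$seq[i], min_loop = min_loop)
    } else {
      fold_external(ds$seq[i], binary = binary)
    }
    ds$structure[i] <- fr$structure
    if (!is.na(fr$energy)) ds$energy[i] <- fr$energy
  }
  ds
}
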