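#' Read RNA sequences from a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file into a hairpin dataset tibble.
#' DNA input is accepted: sequences are uppercased and `T` is transliterated
#' to `U`. Characters outside `{A,C,G,U}` (e.g. `N` or IUPAC ambiguity
#' codes) are kept as `N` and later encoded as an all-zero vector; a warning
#' reports how many records were affected.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq`, `structure` (NA), `energy`
#'   (NA) and `label` (NA) — the dataset format used throughout the package.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "ACGTT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "premir_io_error")
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("malformed FASTA in ", path, ": ", conditionMessage(e)),
        class = "premir_format_error")
    })
  ids <- sub("\\s.*$", "", names(set))
  seqs <- unname(toupper(as.character(set)))
  new_hairpin_dataset(ids, seqs, name = basename(path))
}

#' Write a dataset to FASTA
#'
#' @param ds A hairpin dataset tibble (see [read_fasta()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ds, path) {
  ds <- validate_dataset(ds)
  set <- Biostrings::BStringSet(setNames(ds$seq, ds$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Construct and validate the canonical dataset tibble.
new_hairpin_dataset <- function(ids, seqs, structure = NA_character_,
                                energy = NA_real_, label = NA_integer_,
                                name = NULL) {
  seqs <- toupper(seqs)
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  odd <- grepl("[^ACGU]", seqs)
  if (any(odd)) {
    warn(sprintf(
      "%d record(s) contain non-ACGU symbols; mapped to sentinel 'N' (encoded all-zero)",
      sum(odd)))
    seqs[odd] <- gsub("[^ACGU]", "N", seqs[odd])
  }
  ds <- tibble::tibble(id = as.character(ids), seq = seqs,
                       structure = structure, energy = energy,
                       label = as.integer(label))
  if (!is.null(name)) attr(ds, "dataset_name") <- name
  validate_dataset(ds)
}

validate_dataset <- function(ds) {
  req <- c("id", "seq")
  if (!all(req %in% names(ds))) {
    abort("a hairpin dataset needs at least columns 'id' and 'seq'",
      class = "premir_format_error")
  }
  if (!"structure" %in% names(ds)) ds$structure <- NA_character_
  if (!"energy" %in% names(ds)) ds$energy <- NA_real_
  if (!"label" %in% names(ds)) ds$label <- NA_integer_
  if (anyDuplicated(ds$id)) {
    dup <- unique(ds$id[duplicated(ds$id)])
    abort(paste0("duplicate record id(s): ", paste(head(dup, 5), collapse = ", ")),
      class = "premir_format_error")
  }
  bad <- !nzchar(ds$seq)
  if (any(bad)) {
    abort(paste0("empty sequence for record(s): ",
                 paste(head(ds$id[bad], 5), collapse = ", ")),
      class = "premir_format_error")
  }
  has_str <- !is.na(ds$structure)
  if (any(has_str)) {
    mismatch <- has_str & nchar(ds$structure) != nchar(ds$seq)
    if (any(mismatch)) {
      abort(paste0("structure/sequence length mismatch for record(s): ",
                   paste(head(ds$id[mismatch], 5), collapse = ", ")),
        class = "premir_format_error")
    }
    for (i in which(has_str)) validate_structure(ds$structure[i])
  }
  ds
}

#' Class counts of a labeled dataset
#'
#' @param ds A hairpin dataset tibble.
#' @return Named integer vector `c(positives, negatives)` over labeled
#'   records; unlabeled records are not counted.
#' @export
class_counts <- function(ds) {
  lab <- ds$label[!is.na(ds$label)]
  c(positives = sum(lab == 1L), negatives = sum(lab == 0L))
}

#' Read RNAfold-style plain-text output
#'
#' Parses the three-line-per-record dialect written by `RNAfold`: a FASTA
#' header, the sequence, then the dot-bracket structure followed by the
#' free energy in parentheses (both `"(-1.20)"` and `"( -1.20)"` spacings
#' are accepted; the energy may be absent). Bracket balance and the
#' structure/sequence length invariant are enforced.
#'
#' @param path Path to the structure file.
#' @return A hairpin dataset tibble with `structure` and `energy` filled in.
#' @export
read_rnafold <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("structure file not found: ", path), class = "premir_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) {
    abort("no FASTA headers found in RNAfold-style file",
      class = "premir_format_error")
  }
  recs <- purrr::map(seq_along(hdr), function(i) {
    from <- hdr[i]
    to <- if (i < length(hdr)) hdr[i + 1] - 1 else length(lines)
    block <- lines[from:to]
    if (length(block) < 3) {
      abort(paste0("record ", sub("^>", "", block[1]),
                   ": expected sequence and structure lines"),
        class = "premir_format_error")
    }
    id <- sub("\\s.*$", "", sub("^>", "", block[1]))
    seq <- gsub("\\s", "", block[2])
    strline <- trimws(block[3])
    m <- regmatches(strline, regexec("^([().]+)(\\s*\\(\\s*(-?[0-9.]+)\\s*\\))?\\s*$", strline))[[1]]
    if (length(m) == 0 || !nzchar(m[2])) {
      abort(paste0("record ", id, ": cannot parse structure line: ", strline),
        class = "premir_format_error")
    }
    list(id = id, seq = seq, structure = m[2],
         energy = if (nzchar(m[4])) as.numeric(m[4]) else NA_real_)
  })
  new_hairpin_dataset(
    ids = purrr::map_chr(recs, "id"),
    seqs = purrr::map_chr(recs, "seq"),
    structure = purrr::map_chr(recs, "structure"),
    energy = purrr::map_dbl(recs, "energy"),
    name = basename(path))
}

#' Attach binary labels from a manifest
#'
#' Joins a two-column tab-separated manifest (`id`, `label` in \{0, 1\})
#' onto a dataset by record id.
#'
#' @param ds A hairpin dataset tibble.
#' @param manifest Path to a TSV manifest, or a data frame with columns
#'   `id` and `label`.
#' @return The dataset with its `label` column filled in.
#' @export
attach_labels <- function(ds, manifest) {
  ds <- validate_dataset(ds)
  lab <- if (is.data.frame(manifest)) {
    tibble::as_tibble(manifest)
  } else {
    readr::read_tsv(manifest, col_names = c("id", "label"),
                    col_types = readr::cols(id = "c", label = "i"),
                    progress = FALSE)
  }
  if (nrow(lab) == 0) return(ds)
  if (!all(lab$label %in% c(0L, 1L))) {
    abort("manifest labels must be 0 or 1", class = "premir_format_error")
  }
  missing <- setdiff(lab$id, ds$id)
  if (length(missing) > 0) {
    abort(paste0("manifest id(s) absent from dataset: ",
                 paste(head(missing, 10), collapse = ", ")),
      class = "premir_format_error")
  }
  idx <- match(ds$id, lab$id)
  ds$label <- ifelse(is.na(idx), ds$label, lab$label[idx])
  ds
}

#' Write per-record prediction scores
#'
#' Writes a tab-separated table of `id`, `score` and the predicted label at
#' the given decision threshold (score >= threshold is called positive).
#'
#' @param ds A hairpin dataset tibble.
#' @param scores Numeric vector of probabilities in \[0, 1\], one per record.
#' @param path Output TSV path.
#' @param threshold Decision threshold, default 0.5.
#' @return The prediction tibble, invisibly.
#' @export
write_predictions <- function(ds, scores, path, threshold = 0.5) {
  if (length(scores) != nrow(ds)) {
    abort(sprintf("got %d scores for %d records", length(scores), nrow(ds)),
      class = "premir_format_error")
  }
  out <- tibble::tibble(id = ds$id, score = as.numeric(scores),
                        pred = as.integer(scores >= threshold))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}
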