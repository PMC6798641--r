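#' One-hot encode an RNA sequence
#'
#' Each position becomes a four-dimensional indicator over the alphabet
#' `A, C, G, U` (in that column order); the sentinel `N` encodes as an
#' all-zero row, as do padding rows beyond the sequence end.
#'
#' @param seq RNA string.
#' @param L Pad length; rows `nchar(seq)+1 ... L` are zero. Defaults to the
#'   sequence length.
#' @param truncate Allow sequences longer than `L` to be truncated (with a
#'   warning) instead of erroring.
#' @return A list with `mat` (an `L x 4` binary matrix with columns
#'   `A,C,G,U`) and `mask` (length-`L` 0/1 vector marking real positions).
#' @examples
#' encode_sequence("ACGUU")$mat
#' @export
encode_sequence <- function(seq, L = nchar(seq), truncate = FALSE) {
  seq <- toupper(gsub("T", "U", seq, fixed = TRUE))
  n <- nchar(seq)
  if (n > L) {
    if (!truncate) {
      abort(sprintf("sequence length %d exceeds pad length %d", n, L),
        class = "premir_format_error")
    }
    warn(sprintf("truncating sequence from %d to %d nt", n, L))
    seq <- substr(seq, 1, L)
    n <- L
  }
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "U", "N"))
  if (length(bad) > 0) {
    abort(paste0("invalid residue '", chars[bad[1]], "' at position ", bad[1]),
      class = "premir_format_error")
  }
  mat <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, c("A", "C", "G", "U")))
  idx <- match(chars, c("A", "C", "G", "U"))  # N -> NA -> all-zero row
  keep <- which(!is.na(idx))
  mat[cbind(keep, idx[keep])] <- 1
  list(mat = mat, mask = as.numeric(seq_len(L) <= n))
}

#' One-hot encode a dot-bracket structure
#'
#' Each position becomes a three-dimensional indicator over the states
#' `(`, `.`, `)` (in that column order); padding rows are zero.
#'
#' @param db Dot-bracket string.
#' @inheritParams encode_sequence
#' @return A list with `mat` (an `L x 3` binary matrix with columns
#'   `(`, `.`, `)`) and `mask`.
#' @examples
#' encode_structure("(...)")$mat
#' @export
encode_structure <- function(db, L = nchar(db), truncate = FALSE) {
  n <- nchar(db)
  if (n > L) {
    if (!truncate) {
      abort(sprintf("structure length %d exceeds pad length %d", n, L),
        class = "premir_format_error")
    }
    warn(sprintf("truncating structure from %d to %d positions", n, L))
    db <- substr(db, 1, L)
    n <- L
  }
  chars <- strsplit(db, "")[[1]]
  bad <- which(!chars %in% c("(", ".", ")"))
  if (length(bad) > 0) {
    abort(paste0("invalid structure character '", chars[bad[1]],
                 "' at position ", bad[1]),
      class = "premir_format_error")
  }
  mat <- matrix(0, nrow = L, ncol = 3, dimnames = list(NULL, c("(", ".", ")")))
  idx <- match(chars, c("(", ".", ")"))
  mat[cbind(seq_len(n), idx)] <- 1
  list(mat = mat, mask = as.numeric(seq_len(L) <= n))
}

#' Encode a whole dataset into network-ready arrays
#'
#' Converts every record's sequence and structure into padded one-hot
#' arrays sharing a common length. Sequences are zero-padded on the 3' end
#' to the dataset maximum (or an explicit `L`); zero rows lie outside both
#' one-hot alphabets, so padding is unambiguous, and a mask records the
#' real positions.
#'
#' @param ds A hairpin dataset tibble; every record must carry a structure
#'   (see [fold_dataset()]).
#' @param L Common pad length; `NULL` (default) uses the maximum record
#'   length, capped at `cap`.
#' @param cap Upper bound on the automatic pad length (default 180 nt,
#'   generous for pre-miRNA hairpins of ~60-120 nt).
#' @return An object of class `encoded_hairpins`: a list with arrays
#'   `xseq` (`n x L x 4`), `xstr` (`n x L x 3`), `mask` (`n x L`), integer
#'   vector `length`, `label` (may be NA) and `id`.
#' @export
encode_dataset <- function(ds, L = NULL, cap = 180) {
  ds <- validate_dataset(ds)
  missing <- is.na(ds$structure)
  if (any(missing)) {
    abort(paste0("record(s) without structure: ",
                 paste(head(ds$id[missing], 5), collapse = ", "),
                 "; run fold_dataset() first"),
      class = "premir_format_error")
  }
  lens <- nchar(ds$seq)
  if (is.null(L)) {
    L <- max(lens)
    if (L > cap) {
      abort(sprintf("maximum record length %d exceeds cap %d; set L explicitly", L, cap),
        class = "premir_format_error")
    }
  }
  n <- nrow(ds)
  xseq <- array(0, dim = c(n, L, 4))
  xstr <- array(0, dim = c(n, L, 3))
  mask <- matrix(0, n, L)
  for (i in seq_len(n)) {
    es <- encode_sequence(ds$seq[i], L = L)
    et <- encode_structure(ds$structure[i], L = L)
    xseq[i, , ] <- es$mat
    xstr[i, , ] <- et$mat
    mask[i, ] <- es$mask
  }
  structure(list(xseq = xseq, xstr = xstr, mask = mask,
                 length = lens, label = ds$label, id = ds$id, L = L),
            class = "encoded_hairpins")
}

#' @export
print.encoded_hairpins <- function(x, ...) {
  cat(sprintf("<encoded_hairpins> %d examples, padded to L = %d\n",
              length(x$id), x$L))
  cc <- table(factor(x$label, levels = c(1, 0)))
  cat(sprintf("  labels: %d positive / %d negative / %d unlabeled\n",
              cc[["1"]], cc[["0"]], sum(is.na(x$label))))
  invisible(x)
}

#' Subset an encoded dataset
#'
#' @param x An `encoded_hairpins` object.
#' @param i Integer or logical index over examples.
#' @param ... Unused.
#' @return The subsetted `encoded_hairpins` object.
#' @export
`[.encoded_hairpins` <- function(x, i, ...) {
  structure(list(xseq = x$xseq[i, , , drop = FALSE],
                 xstr = x$xstr[i, , , drop = FALSE],
                 mask = x$mask[i, , drop = FALSE],
                 length = x$length[i], label = x$label[i], id = x$id[i],
                 L = x$L),
            class = "encoded_hairpins")
}

#' @export
length.encoded_hairpins <- function(x) length(x$id)

#' Decode one example back to its sequence and structure strings
#'
#' Inverse of the encoder on the unpadded region (sentinel rows decode to
#' `N`). Mainly used to verify encoding bijectivity.
#'
#' @param enc An `encoded_hairpins` object.
#' @param i Example index.
#' @return A list with `seq` and `structure` strings.
#' @export
decode_example <- function(enc, i) {
  n <- enc$length[i]
  sq <- enc$xseq[i, seq_len(n), , drop = FALSE]
  st <- enc$xstr[i, seq_len(n), , drop = FALSE]
  seq_chars <- apply(sq[1, , , drop = TRUE], 1, function(r) {
    if (sum(r) == 0) "N" else c("A", "C", "G", "U")[which(r == 1)]
  })
  str_chars <- apply(st[1, , , drop = TRUE], 1, function(r) {
    c("(", ".", ")")[which(r == 1)]
  })
  list(seq = paste(seq_chars, collapse = ""),
       structure = paste(str_chars, collapse = ""))
}
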