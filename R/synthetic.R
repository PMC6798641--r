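#' Synthetic hairpin dataset parameters
#'
#' Generative knobs for the built-in simulator: positives are
#' stem-loop-forming sequences (a random 5' arm, a terminal loop, the
#' mutated reverse complement as 3' arm, plus unstructured flanks);
#' negatives are non-hairpin decoys. The default class imbalance of 7.4
#' negatives per positive mirrors the imbalance of curated pre-miRNA
#' screens, and default geometry (18-30 bp stems, 4-10 nt loops, 5-15 nt
#' flanks) gives realistic 50-100 nt records.
#'
#' @param n_pos Number of positive examples (default 500).
#' @param imbalance_ratio Negatives per positive (default 7.4).
#' @param n_neg Number of negatives; defaults to
#'   `round(imbalance_ratio * n_pos)`.
#' @param stem_len Inclusive range of stem arm lengths in bp.
#' @param loop_len Inclusive range of terminal loop lengths in nt.
#' @param flank_len Inclusive range of each flank's length in nt.
#' @param mutation_rate Per-stem-position probability that the 3' arm base
#'   is not the exact complement (default 0.05).
#' @param neg_mode Negative decoy model: `"uniform_random"` (i.i.d.
#'   nucleotides, lengths drawn from the positive length model; default),
#'   `"dinucleotide_shuffle"` (a hairpin sequence shuffled preserving its
#'   dinucleotide counts — a hard, composition- and
#'   neighbour-frequency-matched decoy), or `"composition_matched"`
#'   (i.i.d. draws from the positive pool's mononucleotide frequencies).
#' @param seed RNG seed.
#' @return A `synthetic_params` list.
#' @export
synthetic_params <- function(n_pos = 500, imbalance_ratio = 7.4,
                             n_neg = NULL, stem_len = c(18, 30),
                             loop_len = c(4, 10), flank_len = c(5, 15),
                             mutation_rate = 0.05,
                             neg_mode = c("uniform_random",
                                          "dinucleotide_shuffle",
                                          "composition_matched"),
                             seed = 1) {
  neg_mode <- match.arg(neg_mode)
  if (is.null(n_neg)) n_neg <- round(imbalance_ratio * n_pos)
  stopifnot(n_pos >= 1, n_neg >= 0, mutation_rate >= 0, mutation_rate <= 1,
            stem_len[1] <= stem_len[2], loop_len[1] <= loop_len[2],
            flank_len[1] <= flank_len[2], stem_len[1] >= 1)
  structure(list(n_pos = n_pos, n_neg = n_neg,
                 imbalance_ratio = imbalance_ratio, stem_len = stem_len,
                 loop_len = loop_len, flank_len = flank_len,
                 mutation_rate = mutation_rate, neg_mode = neg_mode,
                 seed = seed),
            class = "synthetic_params")
}

.NUC <- c("A", "C", "G", "U")
.COMP <- c(A = "U", C = "G", G = "C", U = "A")

rand_nt <- function(n, prob = NULL) {
  paste(sample(.NUC, n, replace = TRUE, prob = prob), collapse = "")
}

rint <- function(range) sample(range[1]:range[2], 1)

#' Draw one synthetic hairpin-forming sequence
#'
#' Consumes the current R RNG stream (seed management belongs to
#' [simulate_hairpins()]).
#'
#' @param params A [synthetic_params()].
#' @return The sequence string; its geometry (`stem`, `loop`, flank
#'   lengths) is attached as attributes.
#' @export
make_positive <- function(params = synthetic_params()) {
  s <- rint(params$stem_len)
  l <- rint(params$loop_len)
  f5 <- rint(params$flank_len)
  f3 <- rint(params$flank_len)
  arm5 <- strsplit(rand_nt(s), "")[[1]]
  arm3 <- unname(.COMP[arm5])
  mut <- runif(s) < params$mutation_rate
  if (any(mut)) {
    arm3[mut] <- vapply(arm3[mut],
                        function(b) sample(setdiff(.NUC, b), 1), "")
  }
  seq <- paste0(rand_nt(f5), paste(arm5, collapse = ""), rand_nt(l),
                paste(rev(arm3), collapse = ""), rand_nt(f3))
  structure(seq, stem = s, loop = l, flank5 = f5, flank3 = f3)
}

# Shuffle a sequence preserving its dinucleotide counts: permute each
# residue's successor list, then accept the permutation only if the walk
# from the original start consumes every edge (rejection-sampled Euler
# path). Falls back to the input order if no walk is found.
dinucleotide_shuffle <- function(seq, max_tries = 200) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < 3) return(seq)
  succ <- split(chars[-1], chars[-n])
  for (try in seq_len(max_tries)) {
    perm <- lapply(succ, sample)
    ptr <- lapply(perm, function(x) 1L)
    out <- character(n)
    out[1] <- chars[1]
    cur <- chars[1]
    ok <- TRUE
    for (i in 2:n) {
      nxt_list <- perm[[cur]]
      pos <- ptr[[cur]]
      if (is.null(nxt_list) || pos > length(nxt_list)) {
        ok <- FALSE
        break
      }
      ptr[[cur]] <- pos + 1L
      cur <- nxt_list[pos]
      out[i] <- cur
    }
    if (ok) return(paste(out, collapse = ""))
  }
  warn("dinucleotide shuffle failed to find an Euler path; returning input")
  seq
}

#' Draw one synthetic non-hairpin decoy sequence
#'
#' @param params A [synthetic_params()].
#' @param pos_freq Mononucleotide frequencies of the positive pool
#'   (required for `neg_mode = "composition_matched"`).
#' @param pos_lengths Lengths of the positive pool, resampled for
#'   `composition_matched` decoy lengths.
#' @return The sequence string.
#' @export
make_negative <- function(params = synthetic_params(), pos_freq = NULL,
                          pos_lengths = NULL) {
  switch(params$neg_mode,
    uniform_random = {
      len <- 2 * rint(params$stem_len) + rint(params$loop_len) +
        rint(params$flank_len) + rint(params$flank_len)
      rand_nt(len)
    },
    dinucleotide_shuffle = dinucleotide_shuffle(make_positive(params)),
    composition_matched = {
      if (is.null(pos_freq) || is.null(pos_lengths)) {
        abort("composition_matched decoys need pos_freq and pos_lengths")
      }
      rand_nt(sample(pos_lengths, 1), prob = pos_freq)
    })
}

#' Simulate a labeled synthetic hairpin dataset
#'
#' Generates `n_pos` hairpin-forming positives and `n_neg` decoy
#' negatives, attaches secondary structures with the built-in Nussinov
#' folder, and shuffles the record order. Fully reproducible from
#' `params` (including `params$seed`).
#'
#' @param params A [synthetic_params()].
#' @param fold Attach structures (default TRUE).
#' @return A hairpin dataset tibble with `label` and `structure` filled.
#' @examples
#' ds <- simulate_hairpins(synthetic_params(n_pos = 5, imbalance_ratio = 2))
#' class_counts(ds)
#' @export
simulate_hairpins <- function(params = synthetic_params(), fold = TRUE) {
  set.seed(params$seed)
  pos <- vapply(seq_len(params$n_pos), function(i) make_positive(params), "")
  pos_chars <- strsplit(paste(pos, collapse = ""), "")[[1]]
  pos_freq <- as.numeric(table(factor(pos_chars, levels = .NUC)))
  pos_freq <- pos_freq / sum(pos_freq)
  pos_lengths <- nchar(pos)
  neg <- vapply(seq_len(params$n_neg),
                function(i) make_negative(params, pos_freq, pos_lengths), "")
  ds <- tibble::tibble(
    id = c(sprintf("pos_%05d", seq_along(pos)),
           sprintf("neg_%05d", seq_along(neg))),
    seq = c(pos, neg),
    structure = NA_character_, energy = NA_real_,
    label = c(rep(1L, length(pos)), rep(0L, length(neg))))
  ds <- ds[sample(nrow(ds)), ]
  if (fold) ds <- fold_dataset(ds, method = "nussinov")
  validate_dataset(ds)
}

#' Write a dataset as FASTA + structure file + label manifest
#'
#' Emits exactly the plain-text formats the readers consume:
#' `sequences.fa`, `structures.dbn` (RNAfold-style, energy omitted for
#' Nussinov structures) and `labels.tsv`.
#'
#' @param ds A hairpin dataset tibble.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_dataset_files <- function(ds, dir) {
  ds <- validate_dataset(ds)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "sequences.fa")
  dbn <- file.path(dir, "structures.dbn")
  lab <- file.path(dir, "labels.tsv")
  write_fasta(ds, fa)
  if (any(!is.na(ds$structure))) {
    lines <- purrr::pmap(list(ds$id, ds$seq, ds$structure, ds$energy),
      function(id, seq, st, en) {
        strline <- if (is.na(en)) st else sprintf("%s (%.2f)", st, en)
        c(paste0(">", id), seq, strline)
      })
    writeLines(unlist(lines), dbn)
  } else {
    dbn <- NA_character_
  }
  labeled <- ds[!is.na(ds$label), c("id", "label")]
  readr::write_tsv(labeled, lab, col_names = FALSE, progress = FALSE)
  invisible(c(fasta = fa, structures = dbn, labels = lab))
}
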