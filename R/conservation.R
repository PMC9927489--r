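#' Ordered set of (possibly aligned) amino-acid sequences
#'
#' Lightweight container for the Dut-family sequence pipeline: unique ids,
#' sequences over the 20 amino acids plus gap (\code{-}) and \code{X}, and an
#' aligned flag (aligned sets must be rectangular).
#'
#' @param ids character vector of unique identifiers.
#' @param seqs character vector of sequences (same length as \code{ids}).
#' @param aligned logical: is this a multiple sequence alignment?
#' @return An object of class \code{sequence_set}.
#' @export
sequence_set <- function(ids, seqs, aligned = FALSE) {
  ids <- as.character(ids); seqs <- toupper(as.character(seqs))
  stopifnot(length(ids) == length(seqs))
  if (anyDuplicated(ids)) stop("sequence ids are not unique")
  if (length(seqs)) {
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX.-]", seqs)
    if (any(bad))
      stop("sequence(s) outside the amino-acid alphabet: ",
           paste(utils::head(ids[bad], 3), collapse = ", "))
    if (aligned && length(unique(nchar(seqs))) > 1)
      stop("aligned sequence set is not rectangular")
  }
  structure(list(ids = ids, seqs = seqs, aligned = aligned),
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("sequence_set: ", length(x$ids), " sequence(s)",
      if (x$aligned) paste0(", aligned (", nchar(x$seqs[1] %||% ""),
                            " columns)"),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.sequence_set <- function(x) length(x$ids)

seq_lengths <- function(s) nchar(gsub("[.-]", "", s$seqs))

msa_matrix <- function(s) {
  stopifnot(inherits(s, "sequence_set"), s$aligned)
  m <- do.call(rbind, strsplit(s$seqs, ""))
  m[m == "."] <- "-"
  m
}

#' Read / write FASTA sequence sets
#'
#' Thin wrappers over \code{Biostrings} FASTA I/O; gapped FASTA is read as an
#' alignment when \code{aligned = TRUE} (or auto-detected from gap
#' characters and equal lengths).
#'
#' @param path FASTA file path.
#' @param aligned logical or \code{NA} (auto-detect).
#' @param s a \code{\link{sequence_set}}.
#' @return \code{read_fasta}: a \code{sequence_set}; \code{write_fasta}:
#'   \code{path} invisibly.
#' @export
read_fasta <- function(path, aligned = NA) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*", "", names(ss))
  seqs <- as.character(ss)
  if (is.na(aligned))
    aligned <- length(seqs) > 0 && any(grepl("[.-]", seqs)) &&
      length(unique(nchar(seqs))) == 1
  sequence_set(ids, seqs, aligned = aligned)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(s, path) {
  stopifnot(inherits(s, "sequence_set"))
  ss <- Biostrings::AAStringSet(setNames(s$seqs, s$ids))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Length filtering of a sequence family
#'
#' Keeps sequences whose (ungapped) length lies in
#' \code{[min_len, max_len]} inclusive; the defaults bracket the Dut family,
#' whose members fall mainly between 125 and 225 residues (shorter entries
#' are fragments, longer ones fusions).
#'
#' @param s an unaligned \code{\link{sequence_set}}.
#' @param min_len,max_len inclusive length bounds (residues).
#' @return List with \code{sequences} (filtered set, order preserved) and
#'   \code{removed} (count).
#' @export
length_filter <- function(s, min_len = 125, max_len = 225) {
  stopifnot(inherits(s, "sequence_set"))
  if (s$aligned) stop("length_filter expects an unaligned sequence set")
  len <- seq_lengths(s)
  keep <- len >= min_len & len <= max_len
  list(sequences = sequence_set(s$ids[keep], s$seqs[keep], aligned = FALSE),
       removed = sum(!keep))
}

#' Length-mode detection (bimodality check)
#'
#' Histograms the sequence lengths at \code{bin_width} and reports local
#' maxima holding more than 5\% of the sequences, merging maxima closer than
#' two bins (the taller survives). The Dut family shows two modes, near 150
#' (trimeric) and 190 (monomeric plus insertion-carrying trimeric) residues.
#'
#' @param s a \code{\link{sequence_set}} with at least two sequences.
#' @param bin_width histogram bin width, residues.
#' @param min_mass minimum fraction of sequences a mode must hold.
#' @return \code{data.frame} with \code{location} (bin centre),
#'   \code{count}, sorted by decreasing count.
#' @export
length_modes <- function(s, bin_width = 5, min_mass = 0.05) {
  stopifnot(inherits(s, "sequence_set"), length(s) >= 2)
  len <- seq_lengths(s)
  lo <- floor(min(len) / bin_width) * bin_width
  breaks <- seq(lo, max(len) + bin_width, by = bin_width)
  h <- hist(len, breaks = breaks, right = FALSE, plot = FALSE)
  cnt <- h$counts
  centers <- h$mids
  k <- length(cnt)
  is_max <- vapply(seq_len(k), function(i) {
    left <- if (i > 1) cnt[i - 1] else -Inf
    right <- if (i < k) cnt[i + 1] else -Inf
    cnt[i] >= left && cnt[i] >= right && cnt[i] > 0
  }, logical(1))
  # plateau: keep only the first bin of a run of equal counts
  is_max <- is_max & c(TRUE, cnt[-1] != cnt[-k])
  is_max <- is_max & cnt > min_mass * length(len)
  modes <- data.frame(location = centers[is_max], count = cnt[is_max])
  modes <- modes[order(-modes$count, modes$location), , drop = FALSE]
  # merge modes closer than 2 bins: the taller one absorbs the other
  keep <- rep(TRUE, nrow(modes))
  for (i in seq_len(nrow(modes))) {
    if (!keep[i]) next
    close <- abs(modes$location - modes$location[i]) < 2 * bin_width
    close[seq_len(i)] <- FALSE
    keep[close] <- FALSE
  }
  out <- modes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy identity clustering with representative selection
#'
#' Greedy incremental clustering: sequences are visited in order of
#' decreasing length (ties by input order); each joins the first existing
#' cluster whose representative it matches at \code{>= threshold} pairwise
#' identity, else founds a new cluster. Identity is exact matches divided by
#' the total column count of a global pairwise alignment (gap columns
#' included in the denominator); an optional alignment-coverage floor can be
#' demanded in addition.
#'
#' @param s an unaligned \code{\link{sequence_set}}.
#' @param threshold identity threshold in (0, 1].
#' @param min_coverage optional minimum fraction of the shorter sequence
#'   aligned without terminal gaps (0 disables the constraint).
#' @return An object of class \code{cluster_assignment}: list with
#'   \code{assignment} (data.frame \code{id}, \code{representative}),
#'   \code{representatives} (character vector, founding order) and
#'   \code{threshold}.
#' @export
cluster_representatives <- function(s, threshold = 0.95, min_coverage = 0) {
  stopifnot(inherits(s, "sequence_set"), threshold > 0, threshold <= 1)
  ord <- order(-seq_lengths(s), seq_along(s$ids))
  reps <- integer()
  memb <- integer(length(s$ids))
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      sim <- pairwise_identity(s$seqs[i], s$seqs[r])
      if (sim$identity >= threshold && sim$coverage >= min_coverage) {
        memb[i] <- r; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, i); memb[i] <- i }
  }
  structure(list(
    assignment = data.frame(id = s$ids, representative = s$ids[memb]),
    representatives = s$ids[reps],
    threshold = threshold), class = "cluster_assignment")
}

#' Pairwise global identity of two sequences
#'
#' Identity = exact matches / alignment columns (gaps count as columns) of a
#' global BLOSUM62 alignment; coverage = fraction of the shorter sequence
#' inside the gap-free aligned region.
#'
#' @param a,b amino-acid strings.
#' @return List with \code{identity}, \code{coverage}, \code{columns}.
#' @export
pairwise_identity <- function(a, b) {
  al <- align_global(gsub("[.-]", "", a), gsub("[.-]", "", b))
  cols <- length(al$pattern)
  matches <- sum(al$pattern == al$subject & al$pattern != "-")
  aligned <- sum(al$ia > 0 & al$ib > 0)
  list(identity = matches / cols,
       coverage = aligned / min(sum(al$ia > 0), sum(al$ib > 0)),
       columns = cols)
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment: ", nrow(x$assignment), " sequences in ",
      length(x$representatives), " cluster(s) at identity >= ",
      x$threshold, "\n", sep = "")
  invisible(x)
}

gap_fractions <- function(m) colMeans(m == "-")

# cut-point of the gappyout-style slope rule on one set of per-column gap
# fractions; returns the gap-fraction threshold (columns strictly above it
# are trimmed) or NA when the distribution shows no sharp break
gappy_cut <- function(f) {
  v <- sort(f)
  m <- length(v)
  if (m < 3) return(NA_real_)
  d <- diff(v)
  if (max(d) <= 0) return(NA_real_)
  # trigger only on a clear break in the sorted gap-fraction curve
  if (max(d) < max(0.2, 2 * mean(d))) return(NA_real_)
  s <- v[3:m] - v[1:(m - 2)]          # three-point slope, constant spacing
  i_star <- which.max(s) + 1          # centre of the steepest window
  v[i_star]
}

#' Gap-based alignment-column trimming (gappyout heuristic)
#'
#' Removes the gappy tail of an alignment by the slope rule: per-column gap
#' fractions are sorted, a three-point slope scan over the sorted curve finds
#' the steepest window, and columns gappier than that window's centre are
#' removed — provided the curve shows a clear break (largest consecutive jump
#' at least 0.2 and at least twice the mean jump), so smooth gap
#' distributions are left alone. All-gap ("empty") columns are always
#' removed; gap-free columns are never removed. The rule is applied
#' repeatedly until no column is removed, which makes the operation
#' idempotent.
#'
#' @param msa an aligned \code{\link{sequence_set}}.
#' @return List with \code{msa} (trimmed alignment) and
#'   \code{removed_columns} (indices into the original alignment, ascending).
#' @export
gappyout_trim <- function(msa) {
  m <- msa_matrix(msa)
  orig <- seq_len(ncol(m))
  active <- orig
  removed <- integer()
  repeat {
    f <- gap_fractions(m[, active, drop = FALSE])
    drop <- f >= 1
    cut <- gappy_cut(f)
    if (!is.na(cut)) drop <- drop | f > cut
    if (!any(drop)) break
    removed <- c(removed, active[drop])
    active <- active[!drop]
    if (length(active) == 0) break
  }
  trimmed <- apply(m[, active, drop = FALSE], 1, paste, collapse = "")
  if (length(active) == 0) trimmed <- rep("", nrow(m))
  list(msa = sequence_set(msa$ids, trimmed, aligned = TRUE),
       removed_columns = sort(removed))
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Per-column frequency and information-content profile of an alignment
#'
#' For every column: observed amino-acid frequencies over the non-gap
#' residues, occupancy (non-gap fraction), and information content in bits,
#' \deqn{IC = \log_2 20 - H(column) - e_n,\quad e_n = 19 / (2 \ln 2\, n)}
#' with \eqn{n} the non-gap count (small-sample correction), clamped at 0.
#' This is the quantity a sequence logo draws: symbol heights proportional to
#' frequency, column height to information.
#'
#' @param msa an aligned \code{\link{sequence_set}} with >= 1 sequence.
#' @return An object of class \code{logo_profile}: list with \code{freq}
#'   (20 x L matrix), \code{information} (bits, per column),
#'   \code{occupancy} and \code{n} (non-gap counts).
#' @export
logo_profile <- function(msa) {
  m <- msa_matrix(msa)
  L <- ncol(m)
  freq <- matrix(0, nrow = 20, ncol = L, dimnames = list(AA20, NULL))
  info <- numeric(L)
  occ <- numeric(L)
  nn <- integer(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    occ[j] <- mean(col != "-")
    aa <- col[col %in% AA20]
    n <- length(aa)
    nn[j] <- n
    if (n == 0) next
    p <- tabulate(factor(aa, levels = AA20), nbins = 20) / n
    freq[, j] <- p
    h <- -sum(ifelse(p > 0, p * log2(p), 0))
    info[j] <- max(0, log2(20) - h - 19 / (2 * log(2) * n))
  }
  structure(list(freq = freq, information = info, occupancy = occ, n = nn),
            class = "logo_profile")
}

#' @export
print.logo_profile <- function(x, ...) {
  cat("logo_profile: ", ncol(x$freq), " columns, information ",
      sprintf("%.2f-%.2f bits", min(x$information), max(x$information)),
      "\n", sep = "")
  invisible(x)
}

#' Per-column logo values as a table
#'
#' @param profile a \code{\link{logo_profile}}.
#' @return \code{data.frame} with column index, modal residue and frequency,
#'   information (bits) and occupancy.
#' @export
logo_table <- function(profile) {
  stopifnot(inherits(profile, "logo_profile"))
  modal <- apply(profile$freq, 2, function(p)
    if (all(p == 0)) NA_character_ else AA20[which.max(p)])
  data.frame(column = seq_along(profile$information), modal = modal,
             frequency = apply(profile$freq, 2, max),
             information = profile$information,
             occupancy = profile$occupancy)
}

#' Simple per-column information plot of a logo profile
#'
#' @param x a \code{\link{logo_profile}}.
#' @param ... passed to \code{barplot}.
#' @method plot logo_profile
#' @export
plot.logo_profile <- function(x, ...) {
  graphics::barplot(x$information, names.arg = seq_along(x$information),
                    xlab = "alignment column", ylab = "information (bits)",
                    border = NA, ...)
  invisible(x)
}

#' Conservation summary of named motif columns
#'
#' For each motif column of an alignment: the modal residue, its frequency
#' among non-gap residues, the column information content, and a
#' "highly conserved" flag at a configurable frequency threshold.
#'
#' @param msa an aligned \code{\link{sequence_set}}.
#' @param motif_columns named list mapping motif id to alignment column
#'   indices.
#' @param reference_row optional sequence id whose residues at the motif
#'   columns are reported alongside.
#' @param threshold modal frequency at or above which a column is flagged
#'   conserved.
#' @return \code{data.frame} with \code{motif}, \code{column},
#'   \code{reference} (if requested), \code{modal}, \code{frequency},
#'   \code{information}, \code{conserved}.
#' @export
motif_conservation <- function(msa, motif_columns, reference_row = NULL,
                               threshold = 0.5) {
  if (length(motif_columns) == 0)
    return(data.frame(motif = character(), column = integer(),
                      modal = character(), frequency = numeric(),
                      information = numeric(), conserved = logical()))
  prof <- logo_profile(msa)
  cols <- unlist(motif_columns, use.names = FALSE)
  if (any(cols < 1 | cols > ncol(prof$freq)))
    stop("motif column index outside the alignment")
  motif <- rep(names(motif_columns), lengths(motif_columns))
  lt <- logo_table(prof)[cols, ]
  out <- data.frame(motif = motif, column = cols, modal = lt$modal,
                    frequency = lt$frequency,
                    information = lt$information,
                    conserved = !is.na(lt$modal) & lt$frequency >= threshold)
  if (!is.null(reference_row)) {
    i <- match(reference_row, msa$ids)
    if (is.na(i)) stop("reference id '", reference_row, "' not in alignment")
    chars <- strsplit(msa$seqs[i], "")[[1]]
    out$reference <- chars[cols]
    out <- out[, c("motif", "column", "reference", "modal", "frequency",
                   "information", "conserved")]
  }
  rownames(out) <- NULL
  out
}
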