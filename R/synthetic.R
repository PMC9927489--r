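# Synthetic fixtures with recorded ground truth. Every generator is a pure
# function of (spec, seed): regenerating with the same spec is bit-identical.

helix_ca <- function(n, radius = 2.3, rise = 1.5, twist = 100) {
  # ideal alpha-helical CA trace (the CA geometry of phi/psi -57/-47)
  ang <- (seq_len(n) - 1) * twist * pi / 180
  cbind(x = radius * cos(ang), y = radius * sin(ang),
        z = (seq_len(n) - 1) * rise)
}

ca_chain_atoms <- function(xyz, chain, start_resno = 1) {
  n <- nrow(xyz)
  data.frame(chain = chain, resno = seq.int(start_resno, length.out = n),
             insert = "", resid = "ALA", atom = "CA", element = "C",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occ = 1, b = 20, het = FALSE)
}

#' Specification for a synthetic receptor--ligand--binder complex
#'
#' Defines the toy geometry standing in for a Dut active centre with a bound
#' nucleotide and an approaching repressor helix: a multi-chain receptor of
#' ideal CA helices arranged around the ligand, a small rigid ligand in the
#' central pocket, and a binder helix placed at a stated closest-approach
#' distance.
#'
#' @param receptor_residues residues per receptor chain (>= 3).
#' @param receptor_chains number of receptor chains.
#' @param binder_residues binder helix length (>= 3).
#' @param binder_offset closest heavy-atom distance (Angstrom) between the
#'   binder and the receptor+ligand.
#' @param transform ground-truth \code{\link{rigid_transform}} moving
#'   (receptor + ligand) into the target frame; \code{NULL} draws one from
#'   \code{seed}.
#' @param ligand_jitter_sd Gaussian jitter (Angstrom) applied to the target
#'   copy of the ligand, emulating an analogue with a slightly different
#'   conformation.
#' @param seed integer seed.
#' @return A \code{toy_complex_spec} list.
#' @export
toy_complex_spec <- function(receptor_residues = 30, receptor_chains = 3,
                             binder_residues = 12, binder_offset = 3.5,
                             transform = NULL, ligand_jitter_sd = 0,
                             seed = 1) {
  stopifnot(receptor_residues >= 3, binder_residues >= 3,
            receptor_chains >= 1)
  structure(list(receptor_residues = receptor_residues,
                 receptor_chains = receptor_chains,
                 binder_residues = binder_residues,
                 binder_offset = binder_offset, transform = transform,
                 ligand_jitter_sd = ligand_jitter_sd, seed = seed),
            class = "toy_complex_spec")
}

toy_ligand_atoms <- function(center) {
  # small rigid nucleotide-like atom set (mixed elements, non-planar)
  off <- rbind(
    C1 = c(0.0, 0.0, 0.0), N1 = c(1.4, 0.3, 0.2), O2 = c(-0.7, 1.2, 0.1),
    C2 = c(0.4, -1.3, 0.6), PA = c(2.6, -0.5, 1.0), O3B = c(3.6, 0.6, 1.4))
  ele <- c("C", "N", "O", "C", "P", "O")
  data.frame(chain = "X", resno = 1, insert = "", resid = "LIG",
             atom = rownames(off), element = ele,
             x = off[, 1] + center[1], y = off[, 2] + center[2],
             z = off[, 3] + center[3], occ = 1, b = 20, het = TRUE)
}

#' Generate a toy complex with known ground-truth placement
#'
#' Builds three structures in consistent frames:
#' \itemize{
#'   \item \code{reference}: receptor chains (A, B, ...) + ligand (chain X);
#'   \item \code{complex}: the reference plus a binder helix (chain Z)
#'     placed \code{binder_offset} Angstrom from the receptor+ligand;
#'   \item \code{target}: the reference receptor+ligand moved rigidly by the
#'     ground-truth transform (ligand optionally jittered).
#' }
#' The ground truth (transform and the binder's true coordinates in the
#' target frame) is returned so transfer recovery can be asserted exactly.
#'
#' @param spec a \code{\link{toy_complex_spec}}.
#' @param dir optional directory; when given, \code{target.pdb},
#'   \code{reference.pdb}, \code{complex.pdb} and \code{truth.json} are
#'   written there.
#' @return List with \code{target}, \code{reference}, \code{complex}
#'   (\code{\link{structure3d}}s) and \code{truth} (list: \code{transform},
#'   \code{binder_coords}, \code{spec}).
#' @export
make_toy_complex <- function(spec = toy_complex_spec(), dir = NULL) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  set.seed(spec$seed)
  n_ch <- spec$receptor_chains
  rec <- do.call(rbind, lapply(seq_len(n_ch), function(k) {
    ang <- 2 * pi * (k - 1) / n_ch
    xyz <- helix_ca(spec$receptor_residues)
    xyz[, 1] <- xyz[, 1] + 8 * cos(ang)
    xyz[, 2] <- xyz[, 2] + 8 * sin(ang)
    ca_chain_atoms(xyz, LETTERS[k])
  }))
  height <- (spec$receptor_residues - 1) * 1.5
  lig <- toy_ligand_atoms(c(0, 0, height / 2))
  # binder helix axis along z, pushed out along +x to the stated offset
  bxyz <- helix_ca(spec$binder_residues)
  bxyz[, 3] <- bxyz[, 3] + height / 2 - (spec$binder_residues - 1) * 0.75
  bxyz[, 1] <- bxyz[, 1] + 30
  body <- rbind(as.matrix(rec[, c("x", "y", "z")]),
                as.matrix(lig[, c("x", "y", "z")]))
  d0 <- min(sqrt(outer(bxyz[, 1], body[, 1], "-")^2 +
                 outer(bxyz[, 2], body[, 2], "-")^2 +
                 outer(bxyz[, 3], body[, 3], "-")^2))
  bxyz[, 1] <- bxyz[, 1] - (d0 - spec$binder_offset)
  binder <- ca_chain_atoms(bxyz, "Z")

  reference <- structure3d(rbind(rec, lig), id = "reference")
  complex_structure <- structure3d(rbind(rec, lig, binder), id = "complex")
  tr <- spec$transform
  if (is.null(tr)) tr <- random_transform()
  target <- apply_transform(tr, reference)
  target$id <- "target"
  if (spec$ligand_jitter_sd > 0) {
    i <- target$atoms$het
    target$atoms[i, c("x", "y", "z")] <- target$atoms[i, c("x", "y", "z")] +
      matrix(stats::rnorm(3 * sum(i), sd = spec$ligand_jitter_sd),
             ncol = 3)
  }
  truth <- list(transform = tr,
                binder_coords = apply_transform(tr, as.matrix(
                  binder[, c("x", "y", "z")])),
                spec = spec)
  out <- list(target = target, reference = reference,
              complex = complex_structure, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_structure(out$target, file.path(dir, "target.pdb"))
    write_structure(out$reference, file.path(dir, "reference.pdb"))
    write_structure(out$complex, file.path(dir, "complex.pdb"))
    jsonlite::write_json(
      list(rotation = truth$transform$rotation,
           translation = truth$transform$translation,
           spec = unclass(spec)[!vapply(spec, is.null, logical(1))]),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Specification for a synthetic Dut-like sequence family
#'
#' Emulates the statistics of the Dut family at desk scale: a bimodal length
#' distribution (defaults: modes 150 and 190 residues, 60/40 weights, SD 5),
#' a conserved 125-residue core carrying planted motif columns at stated
#' conservation levels, mode-specific insertions, and (in the aligned
#' variant) rare-insertion columns that are gaps in almost every row. The
#' background model substitutes uniformly away from a random ancestor at a
#' stated per-column identity.
#'
#' @param n number of sequences (>= 2).
#' @param modes,weights,spreads length-mixture parameters (residues).
#' @param motifs \code{data.frame} with \code{motif}, \code{column} (core
#'   column index, 1-125), \code{residue}, \code{level} (conservation
#'   probability).
#' @param background_identity probability a background column retains the
#'   ancestor residue.
#' @param gap_rate fraction of alignment columns that are rare-insertion
#'   (nearly all-gap) columns.
#' @param gap_occupancy occupancy of a rare-insertion column.
#' @param outlier_frac fraction of sequences generated as fragments/fusions
#'   outside the 125-225 band (exercises the length filter).
#' @param seed integer seed.
#' @return A \code{family_spec} list.
#' @export
family_spec <- function(n = 500, modes = c(150, 190), weights = c(0.6, 0.4),
                        spreads = c(5, 5), motifs = default_motif_plant(),
                        background_identity = 0.3, gap_rate = 0.05,
                        gap_occupancy = 0.02, outlier_frac = 0.02,
                        seed = 1) {
  stopifnot(n >= 2, length(modes) == length(weights),
            length(modes) == length(spreads))
  structure(list(n = n, modes = modes, weights = weights / sum(weights),
                 spreads = spreads, motifs = motifs,
                 background_identity = background_identity,
                 gap_rate = gap_rate, gap_occupancy = gap_occupancy,
                 outlier_frac = outlier_frac, seed = seed),
            class = "family_spec")
}

#' @rdname family_spec
#' @export
default_motif_plant <- function()
  data.frame(
    motif = c("I", "II", "II", "III", "III", "IV", "V", "V"),
    column = c(25L, 64L, 65L, 79L, 82L, 105L, 117L, 119L),
    residue = c("G", "R", "S", "D", "Y", "R", "G", "F"),
    level = 0.9)

#' Generate a synthetic Dut-like sequence family
#'
#' Returns the unaligned family (bimodal lengths, core + insertion), a core
#' alignment (125 fully-occupied columns plus rare-insertion gap columns at
#' the stated rate; insertions live outside the core, as they would after
#' building a family alignment on the conserved domain), and the planted
#' truth.
#'
#' @param spec a \code{\link{family_spec}}.
#' @return List with \code{unaligned}, \code{aligned}
#'   (\code{\link{sequence_set}}s), and \code{truth} (list: \code{lengths},
#'   \code{mode_of}, \code{motif_columns} — positions in the aligned
#'   variant —, \code{motifs}, \code{in_range} count for the 125-225 band).
#' @export
make_sequence_family <- function(spec = family_spec()) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  core_len <- 125L
  n <- spec$n
  mode_of <- sample.int(length(spec$modes), n, replace = TRUE,
                        prob = spec$weights)
  len <- round(stats::rnorm(n, spec$modes[mode_of], spec$spreads[mode_of]))
  len <- pmax(len, core_len + 1L)
  n_out <- round(spec$outlier_frac * n)
  if (n_out > 0) {
    idx <- sample.int(n, n_out)
    half <- ceiling(n_out / 2)
    len[idx[seq_len(half)]] <- sample(60:120, half, replace = TRUE)
    if (n_out > half)
      len[idx[(half + 1):n_out]] <- sample(230:300, n_out - half,
                                           replace = TRUE)
    mode_of[idx] <- NA_integer_
  }
  ancestor <- sample(AA20, core_len, replace = TRUE)
  keep_anc <- matrix(stats::runif(n * core_len) < spec$background_identity,
                     nrow = n)
  core <- matrix(sample(AA20, n * core_len, replace = TRUE), nrow = n)
  core[keep_anc] <- matrix(rep(ancestor, each = n), nrow = n)[keep_anc]
  for (k in seq_len(nrow(spec$motifs))) {
    j <- spec$motifs$column[k]
    hit <- stats::runif(n) < spec$motifs$level[k]
    core[hit, j] <- spec$motifs$residue[k]
  }
  insert_len <- pmax(len - core_len, 0L)
  inserts <- vapply(insert_len, function(L)
    paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1))
  core_str <- apply(core, 1, paste, collapse = "")
  # insertion sits between core columns 125 and the C terminus equivalent:
  # append after the core (position is immaterial to the pipeline)
  unaligned <- sequence_set(sprintf("seq%04d", seq_len(n)),
                            paste0(core_str, inserts), aligned = FALSE)
  n_gapcol <- round(spec$gap_rate * core_len / max(1e-9, 1 - spec$gap_rate))
  aln <- core
  gap_positions <- integer(0)
  if (n_gapcol > 0) {
    gap_positions <- sort(sample(core_len + 1L, n_gapcol, replace = TRUE))
    out_cols <- list(); src <- integer()
    for (j in 0:core_len) {
      n_here <- sum(gap_positions == j + 1L)
      if (n_here > 0) for (g in seq_len(n_here)) {
        col <- rep("-", n)
        occ <- stats::runif(n) < spec$gap_occupancy
        col[occ] <- sample(AA20, sum(occ), replace = TRUE)
        out_cols <- c(out_cols, list(matrix(col, ncol = 1)))
        src <- c(src, NA_integer_)
      }
      if (j > 0) {
        out_cols <- c(out_cols, list(core[, j, drop = FALSE]))
        src <- c(src, j)
      }
    }
    aln <- do.call(cbind, out_cols)
    core_to_aln <- match(seq_len(core_len), src)
  } else {
    core_to_aln <- seq_len(core_len)
  }
  aligned <- sequence_set(unaligned$ids,
                          apply(aln, 1, paste, collapse = ""),
                          aligned = TRUE)
  motif_columns <- spec$motifs
  motif_columns$aln_column <- core_to_aln[spec$motifs$column]
  list(unaligned = unaligned, aligned = aligned,
       truth = list(lengths = nchar(unaligned$seqs), mode_of = mode_of,
                    motifs = motif_columns,
                    gap_columns = which(is.na(match(seq_len(ncol(aln)),
                                                    core_to_aln))),
                    in_range = sum(nchar(unaligned$seqs) >= 125 &
                                   nchar(unaligned$seqs) <= 225),
                    ancestor = paste(ancestor, collapse = "")))
}

#' Half-dilution concentration ladder
#'
#' @param top top concentration, M (default 218.7 nM, the capture-protocol
#'   ladder emulated throughout).
#' @param n number of concentrations.
#' @param factor dilution factor between steps.
#' @return Numeric vector of concentrations, M, decreasing.
#' @export
dilution_ladder <- function(top = 218.7e-9, n = 7, factor = 2)
  top / factor^(seq_len(n) - 1)

#' Simulate a sensorgram series over a concentration ladder
#'
#' Thin wrapper over \code{\link{simulate_sensorgram}} across a half-dilution
#' ladder; the noisy variant draws one Gaussian noise track per curve from a
#' single seed.
#'
#' @param p a \code{\link{kinetic_params}}.
#' @param concentrations analyte concentrations, M.
#' @param noise_sd Gaussian noise SD, response units.
#' @param seed integer seed (noise only).
#' @param ... passed to \code{\link{simulate_sensorgram}} (\code{t_assoc},
#'   \code{t_dissoc}, \code{dt}).
#' @return List of \code{\link{sensorgram}}s.
#' @export
make_sensorgrams <- function(p, concentrations = dilution_ladder(),
                             noise_sd = 0, seed = NULL, ...) {
  stopifnot(length(concentrations) >= 2)
  if (!is.null(seed)) set.seed(seed)
  lapply(concentrations, function(cc)
    simulate_sensorgram(p, cc, noise_sd = noise_sd, ...))
}

#' Sensorgram series to/from the long CSV layout
#'
#' Columns: \code{time_s}, \code{response}, \code{concentration_M},
#' \code{phase} (\code{assoc}/\code{dissoc}).
#'
#' @param grams list of \code{\link{sensorgram}}s.
#' @param df long-format \code{data.frame}.
#' @return \code{grams_to_csv}: a \code{data.frame}; \code{grams_from_csv}:
#'   a list of \code{sensorgram}s.
#' @export
grams_to_csv <- function(grams) {
  long <- grams_to_long(grams)
  data.frame(time_s = long$t, response = long$response,
             concentration_M = long$conc,
             phase = ifelse(long$is_assoc, "assoc", "dissoc"))
}

#' @rdname grams_to_csv
#' @export
grams_from_csv <- function(df) {
  stopifnot(all(c("time_s", "response", "concentration_M", "phase") %in%
                names(df)))
  lapply(split(df, df$concentration_M), function(d) {
    a <- d[d$phase == "assoc", ]; b <- d[d$phase == "dissoc", ]
    sensorgram(d$concentration_M[1],
               data.frame(t = a$time_s, response = a$response),
               data.frame(t = b$time_s, response = b$response))
  })
}

#' Generate paired enzyme-assay time courses with a Pi standard curve
#'
#' Linear Pi accumulation at the planted free and inhibited rates over the
#' 0-5 min sampling window, mapped through the standard curve to A630 with
#' additive Gaussian noise.
#'
#' @param v_free,v_inhibited Pi production rates, nmol/min (>= 0).
#' @param curve list with \code{slope} (A630 per nmol Pi) and
#'   \code{intercept}.
#' @param time_min sampling times, minutes.
#' @param noise_sd A630 noise SD.
#' @param seed integer seed.
#' @return List with \code{free}, \code{inhibited}
#'   (\code{\link{assay_timecourse}}s), \code{standards} (data.frame
#'   \code{pi}, \code{absorbance}), and \code{truth} (planted rates and
#'   inhibition percentage).
#' @export
make_assay_timecourse <- function(v_free, v_inhibited,
                                  curve = list(slope = 0.08,
                                               intercept = 0.05),
                                  time_min = seq(0, 5, by = 0.5),
                                  noise_sd = 0, seed = NULL) {
  stopifnot(v_free >= 0, v_inhibited >= 0)
  if (!is.null(seed)) set.seed(seed)
  mk <- function(v, label) {
    a <- curve$intercept + curve$slope * v * time_min
    if (noise_sd > 0) a <- a + stats::rnorm(length(a), sd = noise_sd)
    assay_timecourse(time_min, a, label)
  }
  std_pi <- seq(0, 1.25 * v_free * max(time_min) + 1, length.out = 6)
  standards <- data.frame(pi = std_pi,
                          absorbance = curve$intercept +
                            curve$slope * std_pi)
  list(free = mk(v_free, "free"), inhibited = mk(v_inhibited, "inhibited"),
       standards = standards,
       truth = list(v_free = v_free, v_inhibited = v_inhibited,
                    inhibition = if (v_free > 0)
                      100 * (1 - v_inhibited / v_free) else NA_real_))
}
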