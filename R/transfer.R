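#' Van der Waals radii used for steric-clash scoring
#'
#' Standard element-keyed radii (Angstrom): C 1.70, N 1.55, O 1.52, S 1.80,
#' P 1.80, H 1.20, plus common ions. Unknown elements fall back to 1.70 with
#' a warning.
#'
#' @param elements character vector of element symbols.
#' @return Numeric vector of radii, Angstrom.
#' @export
vdw_radius <- function(elements) {
  tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
           F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, MG = 1.73, ZN = 1.39,
           MN = 1.97, FE = 1.94, "NA" = 2.27, K = 2.75, CA = 2.31, SE = 1.90)
  ele <- toupper(elements)
  r <- unname(tab[ele])
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(ele[is.na(r)]), collapse = ", "),
            ": using 1.7 A van der Waals radius")
    r[is.na(r)] <- 1.70
  }
  r
}

#' Map ligand atoms between two copies (or analogues) of a ligand
#'
#' Pairs the atoms of two single-residue ligands by atom name, applying
#' explicit alias entries for analogue atoms — e.g. the bridging imido
#' nitrogen of alpha,beta-imido-dUTP maps onto the bridging oxygen of dUTP
#' with \code{aliases = c(N3B = "O3B")}. Unmatched atoms are dropped with a
#' warning count.
#'
#' @param target_ligand,ref_ligand atom \code{data.frame}s, each a single
#'   residue (e.g. from \code{\link{select_atoms}} with \code{hetero = TRUE}).
#' @param aliases named character vector mapping reference-ligand atom names
#'   to target-ligand atom names (\code{c(ref_name = "target_name")}); must
#'   be injective.
#' @return An \code{atom_pairs} correspondence (target = A side,
#'   reference = B side).
#' @export
map_ligand_atoms <- function(target_ligand, ref_ligand, aliases = character()) {
  for (lig in list(target_ligand, ref_ligand))
    if (length(unique(paste(lig$chain, lig$resno, lig$insert))) > 1)
      stop("ligand selection spans more than one residue")
  if (length(aliases)) {
    if (is.null(names(aliases)) || anyDuplicated(names(aliases)) ||
        anyDuplicated(aliases))
      stop("ligand atom aliases must be a uniquely named, injective mapping")
  }
  ref_names <- ref_ligand$atom
  hit <- match(ref_names, names(aliases))
  effective <- ifelse(is.na(hit), ref_names, unname(aliases)[hit])
  ia <- match(effective, target_ligand$atom)
  ok <- !is.na(ia)
  dropped <- sum(!ok) + sum(!target_ligand$atom %in% effective)
  if (sum(ok) < 3)
    stop("ligand anchoring failed: only ", sum(ok),
         " atom(s) matched between ligands; >= 3 required")
  if (dropped > 0)
    warning(dropped, " unmatched ligand atom(s) dropped from the anchor")
  structure(list(pairs = cbind(a = ia[ok], b = which(ok)), mode = "atom_name"),
            class = "atom_pairs")
}

#' Ligand-anchored transfer of a binding partner onto a new receptor
#'
#' Places the binder of a solved receptor--binder complex onto a target
#' receptor by anchoring through the bound ligand, the procedure used to
#' model the Stl repressor on a monomeric Dut from the trimeric Dut--Stl
#' complexes:
#' \enumerate{
#'   \item T1: the reference receptor's ligand is superposed onto the target
#'     receptor's ligand (atoms paired by \code{\link{map_ligand_atoms}}),
#'     carrying the whole reference receptor into the target frame;
#'   \item T2: the complex's receptor is superposed (CA pairing) onto the
#'     T1-placed reference receptor, carrying the binder with it;
#'   \item the reference receptor is discarded: the result is the unchanged
#'     target receptor plus the binder in the target frame.
#' }
#' The ligand-superposition residual (\code{anchor_rmsd}) and the
#' receptor-on-receptor residual (\code{receptor_rmsd}) are recorded along
#' with the component transforms.
#'
#' @param target \code{\link{structure3d}}: the new receptor (kept in its own
#'   frame), with its ligand bound.
#' @param reference \code{\link{structure3d}}: a receptor of the same family
#'   as the complex's, with the anchoring ligand bound.
#' @param complex_structure \code{\link{structure3d}}: the solved
#'   receptor--binder complex.
#' @param target_ligand,ref_ligand ligand selectors: lists of arguments for
#'   \code{\link{select_atoms}} (e.g. \code{list(chains = "A",
#'   residue_range = c(300, 300))}); \code{hetero = TRUE} is implied.
#' @param receptor_chains,binder_chains chains of \code{complex_structure}
#'   forming the receptor and the transferred binder.
#' @param ref_receptor_chains chains of \code{reference} paired against the
#'   complex receptor (default: all non-hetero chains).
#' @param aliases ligand atom-name aliases, see \code{\link{map_ligand_atoms}}.
#' @param pairing \code{"residue_number"} when complex and reference share
#'   numbering, \code{"sequence_alignment"} otherwise.
#' @param min_receptor_pairs receptor anchors with fewer CA pairs abort
#'   unless \code{force = TRUE}.
#' @param force proceed on a weak receptor anchor.
#' @return An object of class \code{transfer_model}: list with
#'   \code{receptor}, \code{binder} (placed \code{structure3d}),
#'   \code{anchor_rmsd}, \code{receptor_rmsd}, and \code{provenance}
#'   (transforms \code{t1}, \code{t2} and their composition
#'   \code{binder_placement}).
#' @export
build_transfer_model <- function(target, reference, complex_structure,
                                 target_ligand, ref_ligand,
                                 receptor_chains, binder_chains,
                                 ref_receptor_chains = NULL,
                                 aliases = character(),
                                 pairing = c("residue_number",
                                             "sequence_alignment"),
                                 min_receptor_pairs = 50, force = FALSE) {
  pairing <- match.arg(pairing)
  lig_t <- do.call(select_atoms,
                   c(list(s = target, hetero = TRUE), target_ligand))
  lig_r <- do.call(select_atoms,
                   c(list(s = reference, hetero = TRUE), ref_ligand))
  if (nrow(lig_t) == 0 || nrow(lig_r) == 0)
    stop("ligand selector resolved to zero atoms")
  anchor <- map_ligand_atoms(lig_t, lig_r, aliases = aliases)
  fit1 <- kabsch_superpose(anchor, lig_t, lig_r)
  ref_moved <- apply_transform(fit1$transform, reference)

  ref_ca <- select_atoms(ref_moved, chains = ref_receptor_chains,
                         atom_names = "CA")
  cx_ca <- select_atoms(complex_structure, chains = receptor_chains,
                        atom_names = "CA")
  pairs2 <- pair_receptor_ca(ref_ca, cx_ca, pairing)
  if (nrow(pairs2$pairs) < min_receptor_pairs) {
    msg <- paste0("weak receptor anchor: ", nrow(pairs2$pairs),
                  " CA pairs (< ", min_receptor_pairs, ")")
    if (!force) stop(msg, "; rerun with force = TRUE to accept")
    warning(msg)
  }
  fit2 <- kabsch_superpose(pairs2, ref_ca, cx_ca)

  binder <- structure3d(
    select_atoms(complex_structure, chains = binder_chains, hetero = NA),
    id = paste0(complex_structure$id, "_binder"))
  binder <- apply_transform(fit2$transform, binder)

  out <- list(
    receptor = target, binder = binder,
    anchor_rmsd = fit1$rmsd, receptor_rmsd = fit2$rmsd,
    n_anchor = fit1$n, n_receptor = fit2$n,
    provenance = list(t1 = fit1$transform, t2 = fit2$transform,
                      binder_placement = fit2$transform))
  class(out) <- "transfer_model"
  out
}

# CA pairing between two multi-chain receptor selections: chains are matched
# greedily in file order and pairs concatenated
pair_receptor_ca <- function(ref_ca, cx_ca, pairing) {
  ch_r <- unique(ref_ca$chain); ch_c <- unique(cx_ca$chain)
  n <- min(length(ch_r), length(ch_c))
  ia <- integer(); ib <- integer()
  for (k in seq_len(n)) {
    sa <- ref_ca[ref_ca$chain == ch_r[k], , drop = FALSE]
    sb <- cx_ca[cx_ca$chain == ch_c[k], , drop = FALSE]
    pr <- pair_atoms(sa, sb, mode = pairing)
    ia <- c(ia, which(ref_ca$chain == ch_r[k])[pr$pairs[, 1]])
    ib <- c(ib, which(cx_ca$chain == ch_c[k])[pr$pairs[, 2]])
  }
  structure(list(pairs = cbind(a = ia, b = ib), mode = pairing),
            class = "atom_pairs")
}

#' @export
print.transfer_model <- function(x, ...) {
  cat("transfer_model: binder '", x$binder$id, "' placed on receptor '",
      x$receptor$id, "'\n", sep = "")
  cat(sprintf("  anchor_rmsd   %.4f A over %d ligand atoms\n",
              x$anchor_rmsd, x$n_anchor))
  cat(sprintf("  receptor_rmsd %.4f A over %d CA pairs\n",
              x$receptor_rmsd, x$n_receptor))
  invisible(x)
}

#' Steric-clash detection between two atom groups
#'
#' Flags heavy-atom cross pairs whose distance falls below the sum of the
#' van der Waals radii minus a tolerance (0.4 Angstrom by default, the common
#' crystallographic clash convention). Hydrogens are ignored (crystal
#' structures lack them).
#'
#' @param receptor,binder \code{\link{structure3d}} objects or atom tables.
#' @param tolerance clash tolerance, Angstrom (>= 0).
#' @return An object of class \code{clash_report}: list with \code{clashes}
#'   (data.frame: atom labels, distance, vdw_sum, overlap), \code{clash_count}
#'   and \code{worst_overlap} (0 when clash-free).
#' @export
detect_clashes <- function(receptor, binder, tolerance = 0.4) {
  stopifnot(tolerance >= 0)
  ra <- if (inherits(receptor, "structure3d")) receptor$atoms else receptor
  rb <- if (inherits(binder, "structure3d")) binder$atoms else binder
  ra <- ra[ra$element != "H", , drop = FALSE]
  rb <- rb[rb$element != "H", , drop = FALSE]
  max_sum <- 2 * max(vdw_radius(unique(c(ra$element, rb$element))))
  np <- neighbor_pairs(ra, rb, cutoff = max_sum)
  vdw_sum <- vdw_radius(ra$element[np$i]) + vdw_radius(rb$element[np$j])
  keep <- np$distance < vdw_sum - tolerance
  clashes <- data.frame(
    chain_a = ra$chain[np$i][keep], res_a = ra$resno[np$i][keep],
    atom_a = ra$atom[np$i][keep],
    chain_b = rb$chain[np$j][keep], res_b = rb$resno[np$j][keep],
    atom_b = rb$atom[np$j][keep],
    distance = np$distance[keep], vdw_sum = vdw_sum[keep],
    overlap = (vdw_sum - tolerance - np$distance)[keep])
  structure(list(clashes = clashes, clash_count = nrow(clashes),
                 worst_overlap = if (nrow(clashes)) max(clashes$overlap) else 0,
                 tolerance = tolerance),
            class = "clash_report")
}

#' @export
print.clash_report <- function(x, ...) {
  cat("clash_report: ", x$clash_count, " clash(es) at tolerance ",
      x$tolerance, " A", sep = "")
  if (x$clash_count) cat(sprintf(", worst overlap %.2f A", x$worst_overlap))
  cat("\n")
  invisible(x)
}

#' Summary scores of a transfer model
#'
#' @param m a \code{\link{build_transfer_model}} result.
#' @param contact_cutoff heavy-atom distance (Angstrom) defining an interface
#'   contact.
#' @param tolerance clash tolerance passed to \code{\link{detect_clashes}}.
#' @return List with \code{clash_count}, \code{worst_overlap},
#'   \code{contacts} (interface contact count at the cutoff),
#'   \code{anchor_rmsd} and \code{receptor_rmsd}.
#' @export
score_model <- function(m, contact_cutoff = 4.0, tolerance = 0.4) {
  stopifnot(inherits(m, "transfer_model"))
  cl <- detect_clashes(m$receptor, m$binder, tolerance = tolerance)
  ra <- m$receptor$atoms; ra <- ra[ra$element != "H", , drop = FALSE]
  rb <- m$binder$atoms; rb <- rb[rb$element != "H", , drop = FALSE]
  np <- neighbor_pairs(ra, rb, cutoff = contact_cutoff)
  list(clash_count = cl$clash_count, worst_overlap = cl$worst_overlap,
       contacts = nrow(np), anchor_rmsd = m$anchor_rmsd,
       receptor_rmsd = m$receptor_rmsd)
}
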