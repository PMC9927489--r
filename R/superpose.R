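#' Select atoms from a structure
#'
#' Returns an ordered (file-order) atom table restricted to the requested
#' chains, residue range, and atom names. Waters and heteroatoms are excluded
#' by default so that superposition selections operate on the polymer;
#' ligands are selectable explicitly with \code{hetero = TRUE}.
#'
#' @param s a \code{\link{structure3d}}.
#' @param chains chain identifiers to keep (default: all).
#' @param residue_range length-2 integer vector \code{c(from, to)} of author
#'   residue numbers (inclusive), or \code{NULL}.
#' @param atom_names atom names to keep (e.g. \code{"CA"}), or \code{NULL}.
#' @param hetero if \code{FALSE} (default) HETATM records and waters are
#'   dropped; if \code{TRUE} only HETATM records are returned; if \code{NA}
#'   both are kept.
#' @return Atom \code{data.frame} (possibly empty), in file order.
#' @export
select_atoms <- function(s, chains = NULL, residue_range = NULL,
                         atom_names = NULL, hetero = FALSE) {
  stopifnot(inherits(s, "structure3d"))
  a <- s$atoms
  if (!is.null(chains)) {
    unknown <- setdiff(chains, unique(a$chain))
    if (length(unknown))
      stop("unknown chain(s) ", paste(unknown, collapse = ", "),
           "; valid chains: ", paste(unique(a$chain), collapse = ", "))
    a <- a[a$chain %in% chains, , drop = FALSE]
  }
  if (!is.na(hetero)) {
    a <- if (hetero) a[a$het, , drop = FALSE]
         else a[!a$het & a$resid != "HOH", , drop = FALSE]
  }
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2)
    a <- a[a$resno >= residue_range[1] & a$resno <= residue_range[2], ,
           drop = FALSE]
  }
  if (!is.null(atom_names)) a <- a[a$atom %in% atom_names, , drop = FALSE]
  rownames(a) <- NULL
  a
}

aa3to1 <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | !out %in% LETTERS] <- "X"
  out
}

#' Pair atoms between two selections
#'
#' Builds the atom correspondence consumed by
#' \code{\link{kabsch_superpose}}. Three pairing modes:
#' \describe{
#'   \item{residue_number}{both selections must be single-chain CA lists;
#'     atoms pair on equal (residue number, insertion code).}
#'   \item{atom_name}{both selections must each span one residue; atoms pair
#'     on equal atom name.}
#'   \item{sequence_alignment}{CA selections of possibly non-identical
#'     proteins; a global alignment (BLOSUM62, affine gaps) is computed from
#'     the residue sequences and CA atoms of gap-free columns are paired
#'     (identical or substituted positions alike).}
#' }
#'
#' @param a,b atom \code{data.frame}s (from \code{\link{select_atoms}}).
#' @param mode pairing mode, see above.
#' @return An object of class \code{atom_pairs}: list with \code{pairs}
#'   (2-column index matrix into \code{a} and \code{b}) and \code{mode}.
#' @export
pair_atoms <- function(a, b,
                       mode = c("residue_number", "atom_name",
                                "sequence_alignment")) {
  mode <- match.arg(mode)
  if (mode == "residue_number") {
    for (nm in list(a = a, b = b)) {
      if (length(unique(nm$chain)) > 1)
        stop("residue_number pairing requires single-chain selections")
      if (!all(nm$atom == "CA"))
        stop("residue_number pairing requires CA-only selections")
    }
    ka <- paste(a$resno, a$insert); kb <- paste(b$resno, b$insert)
    ia <- which(ka %in% kb)
    ib <- match(ka[ia], kb)
  } else if (mode == "atom_name") {
    if (length(unique(paste(a$chain, a$resno, a$insert))) > 1 ||
        length(unique(paste(b$chain, b$resno, b$insert))) > 1)
      stop("atom_name pairing requires single-residue selections")
    ia <- which(a$atom %in% b$atom)
    ib <- match(a$atom[ia], b$atom)
  } else {
    if (!all(a$atom == "CA") || !all(b$atom == "CA"))
      stop("sequence_alignment pairing requires CA-only selections")
    sa <- paste(aa3to1(a$resid), collapse = "")
    sb <- paste(aa3to1(b$resid), collapse = "")
    al <- align_global(sa, sb)
    gap_free <- al$ia > 0 & al$ib > 0
    ia <- al$ia[gap_free]; ib <- al$ib[gap_free]
  }
  if (length(ia) < 3)
    stop("insufficient correspondence: only ", length(ia),
         " atom pair(s); >= 3 required")
  structure(list(pairs = cbind(a = ia, b = ib), mode = mode),
            class = "atom_pairs")
}

# global (Needleman-Wunsch) alignment of two amino-acid strings; returns the
# per-column source indices (0 = gap) so callers can extract gap-free columns
align_global <- function(sa, sb) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb), type = "global",
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ia <- ifelse(pa == "-", 0L, cumsum(pa != "-"))
  ib <- ifelse(ps == "-", 0L, cumsum(ps != "-"))
  list(ia = ia, ib = ib, pattern = pa, subject = ps)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation mapping coordinate set B onto
#' coordinate set A with minimal least-squares deviation, via SVD of the
#' cross-covariance matrix. The reflection case is handled by sign-flipping
#' the smallest singular vector, guaranteeing determinant +1.
#'
#' @param pairs an \code{\link{pair_atoms}} correspondence, or \code{NULL} if
#'   \code{coords_a} and \code{coords_b} are already paired row-by-row.
#' @param coords_a,coords_b coordinate matrices (or atom tables /
#'   \code{structure3d}s) for frames A and B; with \code{pairs} supplied these
#'   are indexed by the correspondence.
#' @return List with \code{transform} (a \code{\link{rigid_transform}}
#'   mapping B-frame coordinates onto the A frame), \code{rmsd} (post-fit,
#'   Angstrom) and \code{n} (pair count).
#' @examples
#' xa <- matrix(rnorm(30), 10, 3)
#' xb <- apply_transform(axis_rotation("z", 90, c(1, 2, 3)), xa)
#' fit <- kabsch_superpose(NULL, xa, xb)
#' fit$rmsd  # ~0
#' @export
kabsch_superpose <- function(pairs, coords_a, coords_b) {
  xa <- atom_coords_any(coords_a)
  xb <- atom_coords_any(coords_b)
  if (!is.null(pairs)) {
    stopifnot(inherits(pairs, "atom_pairs"))
    xa <- xa[pairs$pairs[, 1], , drop = FALSE]
    xb <- xb[pairs$pairs[, 2], , drop = FALSE]
  }
  if (nrow(xa) != nrow(xb)) stop("paired coordinate sets differ in size")
  n <- nrow(xa)
  if (n < 3) stop("insufficient correspondence: >= 3 pairs required")
  ca <- colMeans(xa); cb <- colMeans(xb)
  ya <- sweep(xa, 2, ca); yb <- sweep(xb, 2, cb)
  # collinear/degenerate point sets leave the rotation under-determined
  if (svd(ya, nu = 0, nv = 0)$d[2] < 1e-8 * max(1, max(abs(ya))) ||
      svd(yb, nu = 0, nv = 0)$d[2] < 1e-8 * max(1, max(abs(yb))))
    stop("degenerate geometry: point set is (near-)collinear")
  h <- crossprod(yb, ya)            # 3x3 cross-covariance, B -> A
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(ca - rot %*% cb)
  transform <- rigid_transform(rot, tr)
  dev <- ya - yb %*% t(rot)
  list(transform = transform,
       rmsd = sqrt(sum(dev^2) / n),
       n = n)
}

atom_coords_any <- function(x) {
  if (inherits(x, "structure3d") || is.data.frame(x)) atom_coords(x)
  else as.matrix(x)
}

#' Superpose one structure onto another
#'
#' High-level wrapper: selects CA atoms of the requested chains from both
#' structures, pairs them, runs \code{\link{kabsch_superpose}} and optionally
#' returns the transformed mobile structure.
#'
#' @param ref,mobile \code{\link{structure3d}} objects (reference frame A and
#'   mobile frame B).
#' @param chains_ref,chains_mobile chain identifiers used for the fit.
#' @param atom_names atoms used for the fit (default CA).
#' @param mode pairing mode, see \code{\link{pair_atoms}}.
#' @param residue_range_ref,residue_range_mobile optional residue windows.
#' @return List with \code{transform}, \code{rmsd}, \code{n} and
#'   \code{mobile_fitted} (the mobile structure mapped into the reference
#'   frame).
#' @export
superpose <- function(ref, mobile, chains_ref = NULL, chains_mobile = NULL,
                      atom_names = "CA",
                      mode = c("residue_number", "sequence_alignment"),
                      residue_range_ref = NULL, residue_range_mobile = NULL) {
  mode <- match.arg(mode)
  sa <- select_atoms(ref, chains = chains_ref, atom_names = atom_names,
                     residue_range = residue_range_ref)
  sb <- select_atoms(mobile, chains = chains_mobile, atom_names = atom_names,
                     residue_range = residue_range_mobile)
  pr <- pair_atoms(sa, sb, mode = mode)
  fit <- kabsch_superpose(pr, sa, sb)
  fit$mobile_fitted <- apply_transform(fit$transform, mobile)
  fit
}

#' Root-mean-square deviation of two paired coordinate sets (no fitting)
#'
#' @param a,b paired coordinate matrices / atom tables of equal size.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b) {
  xa <- atom_coords_any(a); xb <- atom_coords_any(b)
  stopifnot(nrow(xa) == nrow(xb))
  sqrt(sum((xa - xb)^2) / nrow(xa))
}
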