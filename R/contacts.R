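# Distance-criterion interface typing. The models carry no hydrogens, so
# donor/acceptor status is inferred from residue + atom name and no angle
# terms are applied (PISA-like criteria).

sb_cation <- c("ARG:NH1", "ARG:NH2", "ARG:NE", "LYS:NZ", "HIS:ND1", "HIS:NE2")
sb_anion <- c("ASP:OD1", "ASP:OD2", "GLU:OE1", "GLU:OE2")
hb_donor_side <- c("ARG:NE", "ARG:NH1", "ARG:NH2", "LYS:NZ", "HIS:ND1",
                   "HIS:NE2", "ASN:ND2", "GLN:NE2", "SER:OG", "THR:OG1",
                   "TYR:OH", "TRP:NE1")
hb_acceptor_side <- c("ASP:OD1", "ASP:OD2", "GLU:OE1", "GLU:OE2", "ASN:OD1",
                      "GLN:OE1", "SER:OG", "THR:OG1", "TYR:OH", "HIS:ND1",
                      "HIS:NE2", "MET:SD")

is_hb_donor <- function(resid, atom)
  atom == "N" | paste(resid, atom, sep = ":") %in% hb_donor_side
is_hb_acceptor <- function(resid, atom)
  atom %in% c("O", "OXT") | paste(resid, atom, sep = ":") %in% hb_acceptor_side

#' Type an interface contact from geometry
#'
#' Deterministic distance-based typing of a heavy-atom pair:
#' \itemize{
#'   \item \code{salt_bridge}: one atom is a charged-group nitrogen
#'     (Arg NH1/NH2/NE, Lys NZ, His ND1/NE2) and the other a carboxylate
#'     oxygen (Asp OD1/OD2, Glu OE1/OE2), at \code{<=} the salt-bridge cutoff
#'     (4.0 Angstrom). His is counted as a potential donor (protonation
#'     unknown) and such contacts are flagged.
#'   \item \code{hydrogen_bond}: a donor-capable and an acceptor-capable
#'     heavy atom at \code{<=} the H-bond cutoff (3.5 Angstrom).
#'   \item \code{vdw}: any other pair within the contact cutoff.
#' }
#'
#' @param resid_a,atom_a,resid_b,atom_b residue and atom names (vectorised).
#' @param distance distances, Angstrom.
#' @param cutoffs list with \code{salt} (4.0) and \code{hbond} (3.5).
#' @return Character vector in \code{c("salt_bridge", "hydrogen_bond",
#'   "vdw")}.
#' @export
classify_contact <- function(resid_a, atom_a, resid_b, atom_b, distance,
                             cutoffs = contact_cutoffs()) {
  ka <- paste(resid_a, atom_a, sep = ":")
  kb <- paste(resid_b, atom_b, sep = ":")
  salt <- ((ka %in% sb_cation & kb %in% sb_anion) |
           (kb %in% sb_cation & ka %in% sb_anion)) &
          distance <= cutoffs$salt
  hb <- ((is_hb_donor(resid_a, atom_a) & is_hb_acceptor(resid_b, atom_b)) |
         (is_hb_donor(resid_b, atom_b) & is_hb_acceptor(resid_a, atom_a))) &
        distance <= cutoffs$hbond
  ifelse(salt, "salt_bridge", ifelse(hb, "hydrogen_bond", "vdw"))
}

#' Default interface-contact cutoffs (Angstrom)
#'
#' Heavy-atom van der Waals contact 4.0, hydrogen bond 3.5, salt bridge 4.0
#' — PISA-like distance criteria; configurable in every caller.
#'
#' @param vdw,hbond,salt cutoffs in Angstrom.
#' @return Named list.
#' @export
contact_cutoffs <- function(vdw = 4.0, hbond = 3.5, salt = 4.0)
  list(vdw = vdw, hbond = hbond, salt = salt)

#' Enumerate typed Dut--Stl interface contacts
#'
#' All heavy-atom cross pairs between the two chain groups within the contact
#' cutoff, each typed by \code{\link{classify_contact}}, sorted by Dut
#' residue then distance.
#'
#' @param s a \code{\link{structure3d}} holding the complex.
#' @param dut_chains,stl_chains disjoint chain groups (Dut side first).
#' @param cutoffs see \code{\link{contact_cutoffs}}.
#' @return \code{data.frame} of contact records with columns
#'   \code{dut_chain}, \code{dut_resno}, \code{dut_resid}, \code{dut_atom},
#'   \code{stl_chain}, \code{stl_resno}, \code{stl_resid}, \code{stl_atom},
#'   \code{distance}, \code{type}, \code{his_flag} (His-mediated salt
#'   bridge, protonation unknown).
#' @export
find_contacts <- function(s, dut_chains, stl_chains,
                          cutoffs = contact_cutoffs()) {
  if (length(intersect(dut_chains, stl_chains)))
    stop("dut_chains and stl_chains must be disjoint")
  da <- select_atoms(s, chains = dut_chains)
  sa <- select_atoms(s, chains = stl_chains)
  da <- da[da$element != "H", , drop = FALSE]
  sa <- sa[sa$element != "H", , drop = FALSE]
  empty <- data.frame(
    dut_chain = character(), dut_resno = integer(), dut_resid = character(),
    dut_atom = character(), stl_chain = character(), stl_resno = integer(),
    stl_resid = character(), stl_atom = character(), distance = numeric(),
    type = character(), his_flag = logical())
  if (nrow(da) == 0 || nrow(sa) == 0) {
    warning("empty chain group: no contacts")
    return(empty)
  }
  np <- neighbor_pairs(da, sa, cutoff = cutoffs$vdw)
  if (nrow(np) == 0) return(empty)
  out <- data.frame(
    dut_chain = da$chain[np$i], dut_resno = da$resno[np$i],
    dut_resid = da$resid[np$i], dut_atom = da$atom[np$i],
    stl_chain = sa$chain[np$j], stl_resno = sa$resno[np$j],
    stl_resid = sa$resid[np$j], stl_atom = sa$atom[np$j],
    distance = np$distance)
  out$type <- classify_contact(out$dut_resid, out$dut_atom, out$stl_resid,
                               out$stl_atom, out$distance, cutoffs)
  out$his_flag <- out$type == "salt_bridge" &
    (out$dut_resid == "HIS" | out$stl_resid == "HIS")
  out[order(out$dut_chain, out$dut_resno, out$distance), , drop = FALSE]
}

#' Load or validate a catalytic-motif annotation
#'
#' Trimeric dUTPases carry five conserved catalytic sequence motifs (I--V);
#' motif V is the flexible C-terminal P-loop. Intervals and key residues for
#' the proteins studied here (\code{"mdut"}, \code{"hdut"},
#' \code{"phi11dut"}, \code{"ebvdut"}) ship as JSON under
#' \code{extdata/motifs}; the key residues follow the author numbering used
#' in the structures (e.g. hDut motif III D79/Y82). The monomeric EBV Dut has
#' a reshuffled motif order along its sequence and its spec is flagged
#' \code{reshuffled}.
#'
#' @param spec a bundled protein name, a path to a motif JSON file, or an
#'   already-parsed list.
#' @return An object of class \code{motif_annotation}: list with
#'   \code{protein}, \code{motifs} (data.frame \code{id}, \code{from},
#'   \code{to}) and \code{keys} (data.frame \code{motif}, \code{resno},
#'   \code{aa}).
#' @export
motif_spec <- function(spec) {
  if (is.character(spec) && length(spec) == 1) {
    path <- if (file.exists(spec)) spec
            else system.file("extdata", "motifs", paste0(spec, ".json"),
                             package = "dutstl")
    if (!nzchar(path) || !file.exists(path))
      stop("no bundled motif spec or file for '", spec, "'")
    spec <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  motifs <- data.frame(id = spec$motifs$id, from = spec$motifs$from,
                       to = spec$motifs$to)
  keys <- do.call(rbind, lapply(seq_len(nrow(motifs)), function(i) {
    k <- spec$motifs$keys[[i]]
    if (is.null(k) || NROW(k) == 0) return(NULL)
    data.frame(motif = motifs$id[i], resno = k$resno, aa = k$aa)
  }))
  if (is.null(keys))
    keys <- data.frame(motif = character(), resno = integer(),
                       aa = character())
  ord <- order(motifs$from)
  if (any(motifs$to[ord][-nrow(motifs)] >= motifs$from[ord][-1]))
    stop("motif intervals overlap")
  reshuffled <- isTRUE(spec$reshuffled)
  if (!reshuffled && is.unsorted(motifs$from))
    stop("motifs are not ordered I to V along the sequence")
  structure(list(protein = spec$protein %||% "custom", motifs = motifs,
                 keys = keys, reshuffled = reshuffled),
            class = "motif_annotation")
}

#' Validate a motif annotation against a residue sequence
#'
#' Checks every key residue of the spec (name at author number) against the
#' supplied sequence and returns the validated annotation.
#'
#' @param dut_sequence either a \code{data.frame} with columns \code{resno}
#'   and \code{aa} (1-letter), a named character vector (names = residue
#'   numbers), or a plain 1-letter string numbered from \code{start}.
#' @param spec see \code{\link{motif_spec}}.
#' @param start first residue number when \code{dut_sequence} is a plain
#'   string.
#' @return The validated \code{motif_annotation}.
#' @export
annotate_motifs <- function(dut_sequence, spec, start = 1L) {
  ann <- if (inherits(spec, "motif_annotation")) spec else motif_spec(spec)
  seq_tab <- as_residue_table(dut_sequence, start)
  for (i in seq_len(nrow(ann$keys))) {
    k <- ann$keys[i, ]
    hit <- seq_tab$aa[match(k$resno, seq_tab$resno)]
    if (is.na(hit))
      stop("motif ", k$motif, " key residue ", k$aa, k$resno,
           " is outside the supplied sequence")
    if (hit != k$aa)
      stop("motif ", k$motif, " annotation mismatch: expected ", k$aa,
           " at residue ", k$resno, " but sequence has ", hit)
  }
  ann
}

as_residue_table <- function(x, start = 1L) {
  if (is.data.frame(x)) {
    stopifnot(all(c("resno", "aa") %in% names(x)))
    return(x[, c("resno", "aa")])
  }
  if (length(x) == 1 && is.null(names(x))) x <- strsplit(x, "")[[1]]
  resno <- if (!is.null(names(x))) as.integer(names(x))
           else seq.int(start, length.out = length(x))
  data.frame(resno = resno, aa = as.character(x))
}

#' @export
print.motif_annotation <- function(x, ...) {
  cat("motif_annotation for ", x$protein,
      if (x$reshuffled) " (reshuffled motif order)", ":\n", sep = "")
  for (i in seq_len(nrow(x$motifs))) {
    k <- x$keys[x$keys$motif == x$motifs$id[i], ]
    cat(sprintf("  motif %-3s %d-%d  %s\n", x$motifs$id[i], x$motifs$from[i],
                x$motifs$to[i],
                if (nrow(k)) paste0(k$aa, k$resno, collapse = ", ") else ""))
  }
  invisible(x)
}

#' Stl substrate-mimicry residues
#'
#' The Stl helix-alpha8 residues that occupy the dUTP site of trimeric Duts:
#' Y105, Y106, Y112, Y113, S114, Y116, D117.
#'
#' @return \code{data.frame} with columns \code{aa} and \code{resno}.
#' @export
stl_mimic_residues <- function()
  data.frame(aa = c("Y", "Y", "Y", "Y", "S", "Y", "D"),
             resno = c(105L, 106L, 112L, 113L, 114L, 116L, 117L))

#' Interface report: contacts mapped onto Dut catalytic motifs
#'
#' Aggregates typed contacts into the mimicry analysis: a per-Dut-residue
#' contact table, per-motif contact counts with a touched/untouched flag for
#' each of motifs I--V, and a summary of the Stl mimic residues
#' (\code{\link{stl_mimic_residues}}) with their Dut partners.
#'
#' @param contacts contact \code{data.frame} from \code{\link{find_contacts}}.
#' @param motifs a (validated) \code{motif_annotation}.
#' @return An object of class \code{interface_report}: list with
#'   \code{per_residue}, \code{per_motif} (counts + \code{touched} flags),
#'   \code{mimic} (contacts made by the Stl mimic residues),
#'   \code{unannotated} (contact count outside any motif interval) and
#'   \code{total}.
#' @export
mimicry_report <- function(contacts, motifs) {
  stopifnot(inherits(motifs, "motif_annotation"))
  mtab <- motifs$motifs
  assign_motif <- function(resno) {
    hit <- which(resno >= mtab$from & resno <= mtab$to)
    if (length(hit)) mtab$id[hit[1]] else NA_character_
  }
  motif_of <- if (nrow(contacts))
    vapply(contacts$dut_resno, assign_motif, character(1)) else character()
  ids <- mtab$id
  per_motif <- data.frame(
    motif = ids,
    contacts = vapply(ids, function(m) sum(motif_of == m, na.rm = TRUE),
                      integer(1)))
  per_motif$touched <- per_motif$contacts >= 1
  per_residue <- if (nrow(contacts)) {
    key <- paste(contacts$dut_chain, contacts$dut_resno)
    agg <- lapply(split(seq_len(nrow(contacts)), key), function(idx) {
      data.frame(
        dut_chain = contacts$dut_chain[idx[1]],
        dut_resno = contacts$dut_resno[idx[1]],
        dut_resid = contacts$dut_resid[idx[1]],
        motif = motif_of[idx[1]],
        n_contacts = length(idx),
        partners = paste(unique(paste0(contacts$stl_resid[idx],
                                       contacts$stl_resno[idx])),
                         collapse = ","),
        types = paste(sort(unique(contacts$type[idx])), collapse = ","))
    })
    out <- do.call(rbind, agg)
    out <- out[order(out$dut_chain, out$dut_resno), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else data.frame()
  mim <- stl_mimic_residues()
  mimic <- if (nrow(contacts)) {
    keep <- contacts$stl_resno %in% mim$resno &
      aa3to1(contacts$stl_resid) ==
        mim$aa[match(contacts$stl_resno, mim$resno)]
    contacts[keep, , drop = FALSE]
  } else contacts
  structure(list(per_residue = per_residue, per_motif = per_motif,
                 mimic = mimic,
                 unannotated = sum(is.na(motif_of)),
                 total = nrow(contacts)),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat("interface_report: ", x$total, " contacts (",
      x$unannotated, " outside motif intervals)\n", sep = "")
  for (i in seq_len(nrow(x$per_motif)))
    cat(sprintf("  motif %-3s %3d contact(s)%s\n", x$per_motif$motif[i],
                x$per_motif$contacts[i],
                if (x$per_motif$touched[i]) "  *" else ""))
  cat("  Stl mimic-residue contacts: ", nrow(x$mimic), "\n", sep = "")
  invisible(x)
}
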