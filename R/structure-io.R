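#' Atom-table structure container
#'
#' A \code{structure3d} holds one model of a macromolecular structure as an
#' ordered atom table (chain, residue, atom hierarchy flattened to rows), the
#' representation every geometric stage of the package works on.
#'
#' The atom table has one row per atom with columns:
#' \describe{
#'   \item{chain}{chain identifier}
#'   \item{resno}{author residue number, as deposited}
#'   \item{insert}{insertion code ("" if none)}
#'   \item{resid}{3-letter residue name}
#'   \item{atom}{atom name (e.g. \code{CA}, \code{OD1})}
#'   \item{element}{element symbol}
#'   \item{x, y, z}{coordinates, Angstrom}
#'   \item{occ}{occupancy, in [0, 1]}
#'   \item{b}{isotropic B-factor, Angstrom^2}
#'   \item{het}{\code{TRUE} for HETATM records (ligands, waters, ions)}
#' }
#'
#' @param atoms atom \code{data.frame} as described above.
#' @param id identifier, e.g. a PDB code or file stem.
#' @return An object of class \code{structure3d}.
#' @export
structure3d <- function(atoms, id = "structure") {
  atoms <- as.data.frame(atoms)
  need <- c("chain", "resno", "insert", "resid", "atom", "element",
            "x", "y", "z", "occ", "b", "het")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty structure: no atoms")
  if (!all(is.finite(atoms$x + atoms$y + atoms$z)))
    stop("non-finite atom coordinates")
  if (any(atoms$occ < 0 | atoms$occ > 1))
    stop("occupancy outside [0, 1]")
  if (any(!nzchar(atoms$atom)))
    stop("empty atom name")
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$atom, atoms$het)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, insert, atom) after altloc resolution: ",
         key[which(duplicated(key))[1]])
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  a <- x$atoms
  ch <- table(a$chain)
  cat("structure3d '", x$id, "': ", nrow(a), " atoms, ",
      length(ch), " chain(s) [",
      paste(sprintf("%s:%d", names(ch), as.integer(ch)), collapse = " "),
      "], ", sum(a$het), " hetero atoms\n", sep = "")
  invisible(x)
}

#' Coordinates of an atom table or structure
#'
#' @param x a \code{\link{structure3d}} or atom \code{data.frame}.
#' @return n x 3 numeric matrix of coordinates (Angstrom).
#' @export
atom_coords <- function(x) {
  if (inherits(x, "structure3d")) x <- x$atoms
  as.matrix(x[, c("x", "y", "z")])
}

guess_element <- function(atom_name, resid) {
  # PDB v3 alignment is unreliable in hand-made files: strip digits/primes and
  # take the leading letters; two-letter elements only for common hetero ions.
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  two <- c("FE", "ZN", "MG", "MN", "NA", "CL", "BR", "CA", "SE", "CU", "NI", "CO")
  ifelse(nm %in% two & resid %in% two, nm, substr(nm, 1, 1))
}

resolve_altloc <- function(atoms, alt) {
  # highest occupancy wins; ties resolved by first occurrence (file order)
  alt[is.na(alt)] <- ""
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$atom, atoms$het)
  ord <- order(factor(key, levels = unique(key)), -atoms$occ,
               seq_len(nrow(atoms)))
  first <- !duplicated(key[ord])
  keep <- logical(nrow(atoms))
  keep[ord[first]] <- TRUE
  atoms[keep, , drop = FALSE]
}

#' Read a structure from PDB or mmCIF
#'
#' Reads the first model of a PDB or mmCIF file into a
#' \code{\link{structure3d}}. Alternate locations are resolved to the highest
#' occupancy (ties by first occurrence); heteroatoms are kept and flagged via
#' the \code{het} column. PDB parsing is delegated to
#' \code{\link[bio3d]{read.pdb}}; the mmCIF \code{atom_site} reader is built
#' in.
#'
#' @param path file path.
#' @param format \code{"pdb"}, \code{"cif"}, or \code{"auto"} (by extension).
#' @param id identifier stored on the result; defaults to the file stem.
#' @return A \code{\link{structure3d}}.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  atoms <- if (format == "pdb") read_pdb_atoms(path) else read_cif_atoms(path)
  if (nrow(atoms) == 0) stop("empty structure: no atoms parsed from ", path)
  structure3d(atoms, id = id)
}

read_pdb_atoms <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e)
                    stop("PDB parse error in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  n <- nrow(a)
  if (is.null(n) || n == 0) return(data.frame())
  ins <- a$insert; ins[is.na(ins)] <- ""
  ele <- a$elesy
  bad <- is.na(ele) | !nzchar(trimws(ele))
  ele[bad] <- guess_element(a$elety[bad], a$resid[bad])
  occ <- a$o; occ[is.na(occ)] <- 1
  bfac <- a$b; bfac[is.na(bfac)] <- 0
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), " ", a$chain),
    resno = a$resno, insert = ins, resid = a$resid, atom = a$elety,
    element = toupper(trimws(ele)),
    x = a$x, y = a$y, z = a$z, occ = pmin(1, pmax(0, occ)), b = bfac,
    het = a$type == "HETATM", stringsAsFactors = FALSE)
  resolve_altloc(atoms, a$alt)
}

cif_tokens <- function(line) {
  # whitespace-separated tokens honouring single/double quotes
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  tok <- regmatches(line, list(m))[[1]]
  gsub("^['\"]|['\"]$", "", tok)
}

read_cif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # locate the atom_site loop
  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  as_start <- NA_integer_
  for (ls in loop_starts) {
    j <- ls + 1
    while (j <= length(lines) && grepl("^\\s*#", lines[j])) j <- j + 1
    if (j <= length(lines) && grepl("^_atom_site\\.", trimws(lines[j]))) {
      as_start <- ls; break
    }
  }
  if (is.na(as_start))
    stop("mmCIF parse error in ", path, ": no _atom_site loop found")
  j <- as_start + 1
  fields <- character()
  while (j <= length(lines) && grepl("^_atom_site\\.", trimws(lines[j]))) {
    fields <- c(fields, sub("^_atom_site\\.", "", trimws(lines[j])))
    j <- j + 1
  }
  rows <- list(); k <- 1
  while (j <= length(lines)) {
    ln <- trimws(lines[j])
    if (ln == "" || grepl("^(#|loop_|_[A-Za-z]|data_)", ln)) break
    tok <- cif_tokens(ln)
    if (length(tok) != length(fields))
      stop("mmCIF parse error in ", path, " at line ", j,
           ": expected ", length(fields), " atom_site values, got ", length(tok))
    rows[[k]] <- tok; k <- k + 1
    j <- j + 1
  }
  if (length(rows) == 0) return(data.frame())
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- fields
  pick <- function(...) {
    for (f in c(...)) if (f %in% fields) return(tab[[f]])
    rep(NA_character_, nrow(tab))
  }
  model <- pick("pdbx_PDB_model_num")
  if (!all(is.na(model))) tab <- tab[model == model[1], , drop = FALSE]
  val <- function(v) ifelse(is.na(v) | v %in% c(".", "?"), "", v)
  num <- function(v, default = NA_real_) {
    out <- suppressWarnings(as.numeric(v))
    out[is.na(out)] <- default
    out
  }
  with_tab <- function(f)
    val(if (f %in% fields) tab[[f]] else rep(NA_character_, nrow(tab)))
  chain <- with_tab("auth_asym_id"); lab <- with_tab("label_asym_id")
  chain[!nzchar(chain)] <- lab[!nzchar(chain)]
  resno <- with_tab("auth_seq_id"); lr <- with_tab("label_seq_id")
  resno[!nzchar(resno)] <- lr[!nzchar(resno)]
  resid <- with_tab("auth_comp_id"); lc <- with_tab("label_comp_id")
  resid[!nzchar(resid)] <- lc[!nzchar(resid)]
  aname <- with_tab("auth_atom_id"); la <- with_tab("label_atom_id")
  aname[!nzchar(aname)] <- la[!nzchar(aname)]
  ele <- with_tab("type_symbol")
  bad <- !nzchar(ele)
  ele[bad] <- guess_element(aname[bad], resid[bad])
  atoms <- data.frame(
    chain = chain, resno = as.integer(num(resno)),
    insert = val(with_tab("pdbx_PDB_ins_code")),
    resid = resid, atom = aname, element = toupper(ele),
    x = num(with_tab("Cartn_x")), y = num(with_tab("Cartn_y")),
    z = num(with_tab("Cartn_z")),
    occ = pmin(1, pmax(0, num(with_tab("occupancy"), 1))),
    b = num(with_tab("B_iso_or_equiv"), 0),
    het = with_tab("group_PDB") == "HETATM", stringsAsFactors = FALSE)
  resolve_altloc(atoms, with_tab("label_alt_id"))
}

#' Write a structure as PDB
#'
#' Writes an ATOM/HETATM record per atom (single model, fixed-width PDB
#' columns, coordinates at 0.001 Angstrom precision).
#'
#' @param s a \code{\link{structure3d}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "structure3d"))
  a <- s$atoms
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  # atom-name column alignment: 1-letter elements start in column 14
  nm <- ifelse(nchar(a$atom) < 4 & nchar(a$element) == 1,
               sprintf(" %-3s", a$atom), sprintf("%-4s", a$atom))
  lines <- sprintf(
    "%s%5d %s%s%s%s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(a)) %% 100000, nm, " ",
    sprintf("%-3s", a$resid), sprintf("%2s", substr(a$chain, 1, 1)),
    a$resno, ifelse(nzchar(a$insert), substr(a$insert, 1, 1), " "),
    a$x, a$y, a$z, a$occ, a$b, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
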