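# Independent oracles used to check the package's geometric and sequence
# operations. These deliberately re-derive each quantity by a different
# route (quaternion eigendecomposition, brute-force scans, literal rule
# tables) and never call the implementation they check.

# --- quaternion-eigenvalue rigid superposition (Horn's method) -------------
# returns the proper rotation mapping centred B onto centred A and the
# post-fit rmsd
quat_superpose <- function(xa, xb) {
  ca <- colMeans(xa); cb <- colMeans(xb)
  ya <- sweep(xa, 2, ca); yb <- sweep(xb, 2, cb)
  m <- crossprod(yb, ya)   # m[i,j] = sum_k yb[k,i] * ya[k,j]
  key <- rbind(
    c(m[1, 1] + m[2, 2] + m[3, 3], m[2, 3] - m[3, 2],
      m[3, 1] - m[1, 3], m[1, 2] - m[2, 1]),
    c(m[2, 3] - m[3, 2], m[1, 1] - m[2, 2] - m[3, 3],
      m[1, 2] + m[2, 1], m[1, 3] + m[3, 1]),
    c(m[3, 1] - m[1, 3], m[1, 2] + m[2, 1],
      -m[1, 1] + m[2, 2] - m[3, 3], m[2, 3] + m[3, 2]),
    c(m[1, 2] - m[2, 1], m[1, 3] + m[3, 1],
      m[2, 3] + m[3, 2], -m[1, 1] - m[2, 2] + m[3, 3]))
  q <- eigen(key, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
  dev <- ya - yb %*% t(rot)
  list(rotation = rot, rmsd = sqrt(sum(dev^2) / nrow(xa)),
       translation = as.numeric(ca - rot %*% cb))
}

# --- brute-force all-pairs neighbour scan ----------------------------------
allpairs_oracle <- function(xa, xb, cutoff) {
  is <- list(); js <- list(); ds <- list()
  for (i in seq_len(nrow(xa))) {
    d <- sqrt((xb[, 1] - xa[i, 1])^2 + (xb[, 2] - xa[i, 2])^2 +
              (xb[, 3] - xa[i, 3])^2)
    hit <- which(d <= cutoff)
    if (length(hit)) {
      is[[i]] <- rep.int(i, length(hit)); js[[i]] <- hit; ds[[i]] <- d[hit]
    }
  }
  out <- data.frame(i = unlist(is), j = unlist(js), distance = unlist(ds))
  if (nrow(out) == 0)
    return(data.frame(i = integer(), j = integer(), distance = numeric()))
  out[order(out$i, out$j), ]
}

# --- literal clash rule ----------------------------------------------------
clash_oracle <- function(atoms_a, atoms_b, tolerance = 0.4) {
  radius <- function(e) switch(e, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                               P = 1.80, 1.70)
  hits <- 0; worst <- 0
  for (i in seq_len(nrow(atoms_a))) for (j in seq_len(nrow(atoms_b))) {
    if (atoms_a$element[i] == "H" || atoms_b$element[j] == "H") next
    d <- sqrt((atoms_a$x[i] - atoms_b$x[j])^2 +
              (atoms_a$y[i] - atoms_b$y[j])^2 +
              (atoms_a$z[i] - atoms_b$z[j])^2)
    lim <- radius(atoms_a$element[i]) + radius(atoms_b$element[j]) - tolerance
    if (d < lim) { hits <- hits + 1; worst <- max(worst, lim - d) }
  }
  list(clash_count = hits, worst_overlap = worst)
}

# --- literal contact-typing truth table ------------------------------------
contact_type_oracle <- function(resid_a, atom_a, resid_b, atom_b, d) {
  cation <- function(r, a) (r == "ARG" && a %in% c("NH1", "NH2", "NE")) ||
    (r == "LYS" && a == "NZ") || (r == "HIS" && a %in% c("ND1", "NE2"))
  anion <- function(r, a) (r == "ASP" && a %in% c("OD1", "OD2")) ||
    (r == "GLU" && a %in% c("OE1", "OE2"))
  donor <- function(r, a) a == "N" || cation(r, a) ||
    (r == "ASN" && a == "ND2") || (r == "GLN" && a == "NE2") ||
    (r == "SER" && a == "OG") || (r == "THR" && a == "OG1") ||
    (r == "TYR" && a == "OH") || (r == "TRP" && a == "NE1")
  acceptor <- function(r, a) a %in% c("O", "OXT") || anion(r, a) ||
    (r == "ASN" && a == "OD1") || (r == "GLN" && a == "OE1") ||
    (r == "SER" && a == "OG") || (r == "THR" && a == "OG1") ||
    (r == "TYR" && a == "OH") ||
    (r == "HIS" && a %in% c("ND1", "NE2")) || (r == "MET" && a == "SD")
  if (d <= 4.0 && ((cation(resid_a, atom_a) && anion(resid_b, atom_b)) ||
                   (cation(resid_b, atom_b) && anion(resid_a, atom_a))))
    return("salt_bridge")
  if (d <= 3.5 && ((donor(resid_a, atom_a) && acceptor(resid_b, atom_b)) ||
                   (donor(resid_b, atom_b) && acceptor(resid_a, atom_a))))
    return("hydrogen_bond")
  "vdw"
}

# --- literal gappyout slope rule, exhaustive scan --------------------------
# same stated rule as the package documents, evaluated independently:
# repeat { drop all-gap columns; on sorted gap fractions find the steepest
# three-point window provided max consecutive jump >= max(0.2, 2*mean jump);
# drop columns gappier than the window centre } until stable
gappyout_oracle <- function(mat) {
  removed <- integer(); active <- seq_len(ncol(mat))
  repeat {
    f <- colMeans(mat[, active, drop = FALSE] == "-")
    drop <- f >= 1
    v <- sort(f); m <- length(v)
    if (m >= 3) {
      d <- v[-1] - v[-m]
      if (max(d) > 0 && max(d) >= max(0.2, 2 * mean(d))) {
        best <- -Inf; centre <- NA
        for (i in 2:(m - 1)) {           # exhaustive window scan
          s <- v[i + 1] - v[i - 1]
          if (s > best) { best <- s; centre <- i }
        }
        drop <- drop | f > v[centre]
      }
    }
    if (!any(drop) || length(active) == 0) break
    removed <- c(removed, active[drop])
    active <- active[!drop]
  }
  sort(removed)
}

# --- histogram mode rule, literal ------------------------------------------
length_modes_oracle <- function(len, bin_width = 5, min_mass = 0.05) {
  lo <- floor(min(len) / bin_width) * bin_width
  breaks <- seq(lo, max(len) + bin_width, by = bin_width)
  cnt <- integer(length(breaks) - 1)
  for (x in len) cnt[findInterval(x, breaks)] <- cnt[findInterval(x, breaks)] + 1
  centers <- breaks[-length(breaks)] + bin_width / 2
  k <- length(cnt)
  cand <- c()
  for (i in seq_len(k)) {
    left <- if (i > 1) cnt[i - 1] else -Inf
    right <- if (i < k) cnt[i + 1] else -Inf
    plateau_first <- i == 1 || cnt[i] != cnt[i - 1]
    if (cnt[i] >= left && cnt[i] >= right && plateau_first &&
        cnt[i] > min_mass * length(len))
      cand <- rbind(cand, c(centers[i], cnt[i]))
  }
  if (is.null(cand)) return(numeric())
  cand <- cand[order(-cand[, 2], cand[, 1]), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(cand))) {
      if (j <= i) next
      if (abs(cand[j, 1] - cand[i, 1]) < 2 * bin_width) keep[j] <- FALSE
    }
  }
  cand[keep, 1]
}

# --- small hand-made structure fixtures ------------------------------------
atom_row <- function(chain, resno, resid, atom, element, x, y, z,
                     het = FALSE, occ = 1, b = 20)
  data.frame(chain = chain, resno = resno, insert = "", resid = resid,
             atom = atom, element = element, x = x, y = y, z = z,
             occ = occ, b = b, het = het)

# a 2-chain peptide with Asp side chains, for selection and contact tests
make_asp_fixture <- function() {
  rows <- list()
  for (ch in c("A", "B")) {
    offx <- if (ch == "A") 0 else 20
    for (r in 1:5) {
      base <- (r - 1) * 3.8
      rows[[length(rows) + 1]] <-
        atom_row(ch, r, "ASP", "N", "N", offx + base, 0, 0)
      rows[[length(rows) + 1]] <-
        atom_row(ch, r, "ASP", "CA", "C", offx + base + 1.2, 0.5, 0)
      rows[[length(rows) + 1]] <-
        atom_row(ch, r, "ASP", "O", "O", offx + base + 2.0, -0.8, 0)
      if (r <= 3) {
        rows[[length(rows) + 1]] <-
          atom_row(ch, r, "ASP", "OD1", "O", offx + base + 1.5, 2.0, 0.5)
        rows[[length(rows) + 1]] <-
          atom_row(ch, r, "ASP", "OD2", "O", offx + base + 1.8, 2.2, -0.5)
      }
    }
  }
  structure3d(do.call(rbind, rows), id = "asp_fixture")
}

random_coords <- function(n, spread = 15) matrix(runif(n * 3, 0, spread), n, 3)
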