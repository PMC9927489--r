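two_atom_structure <- function(resid_a, atom_a, ele_a, resid_b, atom_b,
                               ele_b, d) {
  structure3d(rbind(
    atom_row("A", 1, resid_a, atom_a, ele_a, 0, 0, 0),
    atom_row("B", 1, resid_b, atom_b, ele_b, d, 0, 0)), id = "pair")
}

test_that("contact typing follows the stated distance rules", {
  s <- two_atom_structure("ASP", "OD1", "O", "ARG", "NH1", "N", 3.2)
  ct <- find_contacts(s, "A", "B")
  expect_equal(ct$type, "salt_bridge")

  s <- two_atom_structure("GLY", "O", "O", "SER", "OG", "O", 3.4)
  expect_equal(find_contacts(s, "A", "B")$type, "hydrogen_bond")

  expect_equal(classify_contact("LYS", "NZ", "GLU", "OE1", 3.9),
               "salt_bridge")
  expect_equal(classify_contact("LYS", "NZ", "GLU", "OE1", 4.2,
                                contact_cutoffs(vdw = 4.5)), "vdw")
  # His-mediated salt bridges are flagged (protonation unknown)
  s <- two_atom_structure("HIS", "NE2", "N", "ASP", "OD2", "O", 3.5)
  ct <- find_contacts(s, "A", "B")
  expect_equal(ct$type, "salt_bridge")
  expect_true(ct$his_flag)
})

test_that("typing matches an exhaustive rule truth table", {
  probes <- expand.grid(
    a = c("ASP:OD1", "GLU:OE2", "ARG:NH1", "LYS:NZ", "HIS:ND1", "SER:OG",
          "THR:OG1", "ASN:ND2", "GLN:OE1", "TYR:OH", "ALA:CB", "GLY:O",
          "LEU:N", "MET:SD", "TRP:NE1", "PHE:CZ"),
    b = c("ASP:OD2", "GLU:OE1", "ARG:NE", "LYS:NZ", "HIS:NE2", "SER:OG",
          "ASN:OD1", "GLN:NE2", "VAL:CG1", "ILE:O", "CYS:N", "TYR:OH"),
    d = c(3.0, 3.7, 4.2), stringsAsFactors = FALSE)
  split2 <- function(x) do.call(rbind, strsplit(x, ":"))
  pa <- split2(probes$a); pb <- split2(probes$b)
  got <- classify_contact(pa[, 1], pa[, 2], pb[, 1], pb[, 2], probes$d,
                          contact_cutoffs(vdw = 4.5))
  want <- vapply(seq_len(nrow(probes)), function(i)
    contact_type_oracle(pa[i, 1], pa[i, 2], pb[i, 1], pb[i, 2], probes$d[i]),
    character(1))
  expect_equal(got, want)
})

test_that("find_contacts equals the all-pairs scan on a toy interface", {
  set.seed(41)
  res_pool <- c("ASP", "ARG", "SER", "TYR", "ALA", "GLU", "LYS", "GLY")
  atom_pool <- list(ASP = c("N", "CA", "O", "OD1", "OD2"),
                    ARG = c("N", "CA", "O", "NE", "NH1", "NH2"),
                    SER = c("N", "CA", "O", "OG"),
                    TYR = c("N", "CA", "O", "OH"),
                    ALA = c("N", "CA", "O", "CB"),
                    GLU = c("N", "CA", "O", "OE1", "OE2"),
                    LYS = c("N", "CA", "O", "NZ"),
                    GLY = c("N", "CA", "O"))
  mk <- function(chain, n, offx) {
    rows <- list()
    for (r in seq_len(n)) {
      resid <- sample(res_pool, 1)
      for (at in atom_pool[[resid]])
        rows[[length(rows) + 1]] <- atom_row(
          chain, r, resid, at, substr(at, 1, 1),
          offx + runif(1, 0, 6), runif(1, 0, 6), runif(1, 0, 6))
    }
    do.call(rbind, rows)
  }
  da <- mk("A", 4, 0); sb <- mk("B", 4, 4)
  s <- structure3d(rbind(da, sb), id = "iface")
  got <- find_contacts(s, "A", "B")
  want <- allpairs_oracle(atom_coords(da), atom_coords(sb), 4.0)
  expect_equal(nrow(got), nrow(want))
  expect_equal(sort(got$distance), sort(want$distance), tolerance = 1e-12)
  for (i in seq_len(nrow(got)))
    expect_equal(got$type[i],
                 contact_type_oracle(got$dut_resid[i], got$dut_atom[i],
                                     got$stl_resid[i], got$stl_atom[i],
                                     got$distance[i]))
  expect_error(find_contacts(s, "A", "A"), "disjoint")
  expect_warning(ct0 <- find_contacts(
    structure3d(da, id = "x"), "A", character(0)), "empty")
  expect_equal(nrow(ct0), 0)
})

test_that("bundled motif specifications load and validate", {
  for (prot in c("mdut", "hdut", "phi11dut", "ebvdut")) {
    ann <- motif_spec(prot)
    expect_s3_class(ann, "motif_annotation")
    expect_true(all(ann$motifs$from <= ann$motifs$to))
  }
  hd <- motif_spec("hdut")
  expect_true(all(c("II", "III", "IV", "V") %in% hd$motifs$id))
  expect_true(all(c(62, 63) %in% hd$keys$resno[hd$keys$motif == "II"]))
  expect_true(all(c(79, 82) %in% hd$keys$resno[hd$keys$motif == "III"]))
  expect_true(all(c(127, 130, 133, 134, 136) %in%
                  hd$keys$resno[hd$keys$motif == "V"]))
})

test_that("motif annotation validates key residues against the sequence", {
  seq_tab <- data.frame(resno = 58:140, aa = "A")
  keys <- motif_spec("hdut")$keys
  seq_tab$aa[match(keys$resno, seq_tab$resno)] <- keys$aa
  ann <- annotate_motifs(seq_tab, "hdut")
  expect_s3_class(ann, "motif_annotation")

  bad <- seq_tab
  bad$aa[bad$resno == 79] <- "G"   # spec expects D79
  expect_error(annotate_motifs(bad, "hdut"), "D.*79.*G")
  short <- seq_tab[seq_tab$resno <= 100, ]
  expect_error(annotate_motifs(short, "hdut"), "outside")
})

test_that("generator-planted motifs validate against generated sequences", {
  fam <- make_sequence_family(family_spec(n = 40, seed = 13))
  plant <- fam$truth$motifs
  spec <- list(protein = "synthetic", motifs = data.frame(
    id = c("I", "II", "III", "IV", "V"),
    from = c(20, 60, 75, 100, 115), to = c(30, 70, 90, 112, 125)))
  spec$motifs$keys <- lapply(spec$motifs$id, function(m) {
    k <- plant[plant$motif == m, ]
    data.frame(resno = k$column, aa = k$residue)
  })
  # a sequence that realised every planted residue validates cleanly
  m <- do.call(rbind, strsplit(substr(fam$unaligned$seqs, 1, 125), ""))
  ok <- which(apply(m[, plant$column, drop = FALSE], 1,
                    function(r) all(r == plant$residue)))[1]
  expect_false(is.na(ok))
  ann <- annotate_motifs(substr(fam$unaligned$seqs[ok], 1, 125),
                         motif_spec(spec))
  expect_equal(nrow(ann$keys), nrow(plant))
})

test_that("mimicry report aggregates motif flags and mimic residues", {
  mk_contact <- function(dut_resno, stl_resno, stl_resid = "TYR",
                         type = "hydrogen_bond")
    data.frame(dut_chain = "A", dut_resno = dut_resno, dut_resid = "ASP",
               dut_atom = "OD1", stl_chain = "D", stl_resno = stl_resno,
               stl_resid = stl_resid, stl_atom = "OH", distance = 3.2,
               type = type, his_flag = FALSE)
  motifs <- motif_spec("hdut")
  contacts <- rbind(mk_contact(62, 113), mk_contact(79, 112),
                    mk_contact(105, 117, "ASP", "salt_bridge"),
                    mk_contact(50, 40, "GLY"))   # outside any motif
  rep <- mimicry_report(contacts, motifs)
  flags <- setNames(rep$per_motif$touched, rep$per_motif$motif)
  expect_true(all(flags[c("II", "III", "IV")]))
  expect_false(any(flags[c("I", "V")]))
  expect_equal(sum(rep$per_motif$contacts) + rep$unannotated, rep$total)
  expect_equal(nrow(rep$mimic), 3)   # Y113, Y112, D117; not the Gly40 row

  empty <- mimicry_report(contacts[0, ], motifs)
  expect_false(any(empty$per_motif$touched))
  expect_equal(empty$total, 0)
})

test_that("interface report is invariant to atom order and rigid motion", {
  toy <- make_toy_complex(toy_complex_spec(seed = 42, binder_offset = 3.0))
  motifs <- motif_spec(list(protein = "toy", motifs = data.frame(
    id = c("I", "II"), from = c(1, 16), to = c(15, 30),
    keys = I(list(NULL, NULL)))))
  base <- find_contacts(toy$complex, c("A", "B", "C"), "Z")
  rep1 <- mimicry_report(base, motifs)

  shuf <- toy$complex
  set.seed(1)
  shuf$atoms <- shuf$atoms[sample(nrow(shuf$atoms)), ]
  rep2 <- mimicry_report(find_contacts(shuf, c("A", "B", "C"), "Z"), motifs)
  expect_equal(rep1$per_motif$contacts, rep2$per_motif$contacts)
  expect_equal(rep1$total, rep2$total)

  moved <- apply_transform(random_transform(), toy$complex)
  rep3 <- mimicry_report(find_contacts(moved, c("A", "B", "C"), "Z"), motifs)
  expect_equal(rep1$per_motif$contacts, rep3$per_motif$contacts)
  expect_equal(rep1$total, rep3$total)
})
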