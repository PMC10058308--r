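# Brute-force recount of donor-acceptor pairs below the distance criterion,
# using the test's own minimal dictionary for the Watson-Crick edge.
oracle_wc_hbonds <- function(model) {
  at <- model$atoms
  xyz <- model$xyz
  donors <- list(G = c("N1", "N2"), C = c("N4"))
  acceptors <- list(G = c("O6", "N3", "N7"), C = c("O2", "N3"))
  hits <- 0
  for (i in seq_len(nrow(at))) for (j in seq_len(nrow(at))) {
    if (at$reskey[i] == at$reskey[j]) next
    if (!(at$elety[i] %in% donors[[at$resid[i]]])) next
    if (!(at$elety[j] %in% acceptors[[at$resid[j]]])) next
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < 3.35) hits <- hits + 1
  }
  hits
}

test_that("an idealized Watson-Crick G-C pair forms exactly three hbonds", {
  wc <- make_wc_pair()
  hb <- find_hbonds(wc)
  expect_equal(nrow(hb), 3)
  expect_equal(nrow(hb), oracle_wc_hbonds(wc))
  expect_setequal(paste(hb$atom_i, hb$atom_j),
                  c("N1 N3", "N2 O2", "N4 O6"))
  expect_true(all(hb$category == "BB"))
  expect_true(all(hb$distance < 3.35))
})

test_that("hydrogen-bond distance criteria are strict", {
  # donor G:N1 vs acceptor C:O2 like geometry at controlled distances
  mk <- function(da) as_rpflex_model(
    data.frame(elety = c("N3", "O2"), resid = c("U", "C"), chain = "A",
               resno = c(1, 5), stringsAsFactors = FALSE),
    rbind(c(0, 0, 0), c(da, 0, 0)))
  expect_equal(nrow(find_hbonds(mk(3.34))), 1)
  expect_equal(nrow(find_hbonds(mk(3.35))), 0) # boundary excluded
  expect_equal(nrow(find_hbonds(mk(2.9))), 1)
  expect_equal(nrow(find_hbonds(mk(1.7))), 0)  # covalent-distance guard

  # explicit hydrogen: H-acceptor must also be < 2.7
  mkh <- function(hx) as_rpflex_model(
    data.frame(elety = c("N3", "H3", "O2"), resid = c("U", "U", "C"),
               chain = "A", resno = c(1, 1, 5), stringsAsFactors = FALSE),
    rbind(c(0, 0, 0), c(hx, 0, 0), c(3.0, 0, 0)))
  expect_equal(nrow(find_hbonds(mkh(1.0))), 1)   # H-A = 2.0: accepted
  expect_equal(nrow(find_hbonds(mkh(0.1))), 0)   # H-A = 2.9: rejected
})

test_that("vdW contacts exclude hbond pairs and covalent linkages", {
  wc <- make_wc_pair()
  hb <- find_hbonds(wc)
  vd <- find_vdw(wc, hbonds = hb)
  key <- function(df) paste(
    pmin(paste(df$res_i, df$atom_i), paste(df$res_j, df$atom_j)),
    pmax(paste(df$res_i, df$atom_i), paste(df$res_j, df$atom_j)))
  expect_length(intersect(key(hb), key(vd)), 0)
  expect_true(all(vd$distance < 3.9))

  # strict 3.9 boundary and the O3'-P backbone exclusion
  mk <- function(d, a1 = "C2", a2 = "C2") as_rpflex_model(
    data.frame(elety = c(a1, a2), resid = "G", chain = "A", resno = c(1, 2),
               stringsAsFactors = FALSE),
    rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_equal(nrow(find_vdw(mk(3.5), hbonds = find_hbonds(mk(3.5)))), 1)
  expect_equal(nrow(find_vdw(mk(3.9), hbonds = find_hbonds(mk(3.9)))), 0)
  bb <- mk(1.6, "O3'", "P")
  expect_equal(nrow(find_vdw(bb, hbonds = find_hbonds(bb))), 0)
})

test_that("contact categories map chemical-group pairs", {
  mod <- as_rpflex_model(
    data.frame(
      elety = c("O2'", "OP1", "N1", "NH1", "C1"),
      resid = c("G", "C", "A", "ARG", "LIG"),
      chain = c("A", "A", "A", "B", "C"),
      resno = c(1, 2, 3, 1, 1),
      kind = c("nucleotide", "nucleotide", "nucleotide", "amino_acid",
               "ligand"),
      stringsAsFactors = FALSE),
    matrix(0, 5, 3))
  rec <- data.frame(
    res_i = c("A/1", "A/1", "A/1", "A/3"),
    res_j = c("A/2", "B/1", "C/1", "C/1"),
    atom_i = c("O2'", "O2'", "O2'", "N1"),
    atom_j = c("OP1", "NH1", "C1", "C1"),
    stringsAsFactors = FALSE)
  expect_equal(categorize(rec, mod),
               c("PR", "charged", "ligand-backbone", "ligand-base"))
})

test_that("summary percentages are normalized per contact type", {
  rec <- data.frame(
    res_i = "A/1", res_j = "A/2", atom_i = "X", atom_j = "Y",
    distance = 3, type = rep(c("hbond", "vdw"), c(4, 3)),
    category = c("BB", "BB", "RR", "RR", "BB", "PR", "RR"),
    stringsAsFactors = FALSE)
  s <- summarize_contacts(rec)
  expect_equal(s$hbond$percent[s$hbond$category == "BB"], 50)
  expect_equal(s$hbond$percent[s$hbond$category == "RR"], 50)
  expect_equal(sum(s$hbond$percent), 100, tolerance = 0.1)
  expect_equal(sum(s$vdw$percent), 100, tolerance = 0.1)
  # independent tally oracle
  tab <- table(rec$category[rec$type == "vdw"])
  for (cat in names(tab))
    expect_equal(s$vdw$count[s$vdw$category == cat], as.integer(tab[[cat]]))
  expect_warning(z <- summarize_contacts(rec[0, ]), "no contact")
  expect_equal(nrow(z$hbond), 0)
})

test_that("a contact pair is symmetric in its two residues", {
  wc <- make_wc_pair()
  hb <- find_hbonds(wc)
  # every record's reversed pair would categorize identically
  rev <- hb
  rev[c("res_i", "res_j", "atom_i", "atom_j")] <-
    hb[c("res_j", "res_i", "atom_j", "atom_i")]
  expect_equal(categorize(rev, wc), categorize(hb, wc))
})
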