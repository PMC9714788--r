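# Adduct-aware accurate-mass annotation and glycan matching.

test_that("ppm_error follows the signed convention", {
  expect_equal(ppm_error(200, 200), 0)
  expect_equal(ppm_error(200.0008, 200.0000), 4, tolerance = 1e-6)
  expect_equal(ppm_error(199.9992, 200.0000), -4, tolerance = 1e-6)
  expect_error(ppm_error(100, 0), "> 0")
})

test_that("the 9-AA matrix peak annotates to its M-H ion within 1 ppm", {
  db <- load_metabolite_db()
  annos <- annotate_peaks(data.frame(mz = 193.0771), db, tol_ppm = 4)
  hit <- annos[annos$name == "9-aminoacridine", ]
  expect_equal(nrow(hit), 1L)
  expect_identical(hit$adduct, "M-H")
  expect_lt(abs(hit$ppm), 1)
  # empty table annotates nothing
  expect_equal(nrow(annotate_peaks(data.frame(mz = 193.0771), db[0, ])), 0L)
})

test_that("annotation equals the brute-force db x adduct sweep", {
  db <- load_metabolite_db()
  set.seed(21)
  # peaks at exact adduct positions, slightly jittered, plus decoys
  rows <- sample(nrow(db), 25)
  labels <- sample(adduct_rules()$label, 25, replace = TRUE)
  true_mz <- vapply(seq_len(25), function(i) {
    adduct_mz(db$mass[rows[i]], labels[i])
  }, numeric(1))
  peaks <- data.frame(mz = sort(c(true_mz * (1 + runif(25, -2e-6, 2e-6)),
                                  runif(10, 75, 1100))))
  got <- annotate_peaks(peaks, db, tol_ppm = 4)

  oracle <- list()
  for (p in peaks$mz) {
    for (r in seq_len(nrow(db))) {
      for (a in adduct_rules()$label) {
        theo <- adduct_mz(db$mass[r], a)
        ppm <- (p - theo) / theo * 1e6
        if (abs(ppm) <= 4) {
          oracle[[length(oracle) + 1L]] <-
            data.frame(peak_mz = p, id = db$id[r], adduct = a)
        }
      }
    }
  }
  oracle <- do.call(rbind, oracle)
  oracle <- oracle[order(oracle$peak_mz, oracle$id, oracle$adduct), ]
  got_key <- got[order(got$peak_mz, got$id, got$adduct),
                 c("peak_mz", "id", "adduct")]
  expect_equal(unname(as.matrix(got_key)), unname(as.matrix(oracle)))
})

test_that("annotation output is invariant under db row order", {
  db <- load_metabolite_db()
  peaks <- data.frame(mz = c(193.0771, 179.0561, 225.0000))
  a1 <- annotate_peaks(peaks, db)
  set.seed(3)
  a2 <- annotate_peaks(peaks, db[sample(nrow(db)), ])
  rownames(a1) <- rownames(a2) <- NULL
  expect_equal(a1, a2)
})

test_that("tightening the tolerance never adds annotations", {
  db <- load_metabolite_db()
  set.seed(14)
  peaks <- data.frame(mz = sort(runif(60, 75, 1100)))
  wide <- annotate_peaks(peaks, db, tol_ppm = 4)
  narrow <- annotate_peaks(peaks, db, tol_ppm = 2)
  key <- function(a) paste(a$peak_mz, a$id, a$adduct)
  expect_true(all(key(narrow) %in% key(wide)))
  expect_lte(nrow(narrow), nrow(wide))
})

test_that("filter_exogenous removes exactly the flagged records", {
  db <- load_metabolite_db()
  decoys <- db$id[!db$endogenous]
  peaks <- data.frame(mz = c(
    adduct_mz(db$mass[db$name == "atrazine"], "M-H"),
    adduct_mz(db$mass[db$name == "glucose"], "M-H"),
    adduct_mz(db$mass[db$name == "9-aminoacridine"], "M-H")))
  annos <- annotate_peaks(peaks, db)
  kept <- filter_exogenous(annos)
  expect_true(all(kept$endogenous))
  expect_false(any(kept$id %in% decoys))
  expect_true("OSM0001" %in% kept$id || "glucose" %in% kept$name)
  # all-endogenous input passes unchanged
  endo <- annos[annos$endogenous, ]
  rownames(endo) <- NULL
  expect_equal(filter_exogenous(endo), endo)
  # all-exogenous input empties
  exo <- annos[!annos$endogenous, ]
  expect_equal(nrow(filter_exogenous(exo)), 0L)
})

test_that("glycan annotation labels compositions in nomenclature", {
  # HexNAc + sulfate as [M-H]-
  target <- adduct_mz(glycan_fragment_mass(
    glycan_composition(c(HexNAc = 1), c(S = 1))), "M-H")
  annos <- annotate_glycans(data.frame(mz = target), tol_ppm = 4)
  expect_true("HexNAc1S1" %in% annos$id)
  expect_true(all(annos$adduct == "M-H"))
  # zero tolerance keeps only the exact synthetic mass
  exact <- annotate_glycans(data.frame(mz = target), tol_ppm = 0)
  expect_true(all(abs(exact$ppm) == 0))
  expect_true("HexNAc1S1" %in% exact$id)
  # zero bounds enumerate nothing
  none <- annotate_glycans(data.frame(mz = target),
                           max_residues = c(Hex = 0), max_mods = c(S = 0))
  expect_equal(nrow(none), 0L)
  # enumeration cap warns
  expect_warning(
    annotate_glycans(data.frame(mz = target),
                     max_residues = c(Hex = 8, HexNAc = 8, HexA = 8,
                                      HexN = 8, dHex = 8, NeuAc = 8,
                                      NeuGc = 8, Pen = 8),
                     max_compositions = 100),
    "capped")
})

test_that("planted phantom identities are recovered perfectly at 4 ppm", {
  truth <- small_truth()
  db <- load_metabolite_db()
  planted <- truth$peaks[truth$peaks$home != "background", ]
  set.seed(6)
  observed <- data.frame(mz = planted$mz * (1 + runif(nrow(planted),
                                                      -9e-7, 9e-7)))
  annos <- annotate_peaks(observed, db, tol_ppm = 4)
  hit <- vapply(seq_len(nrow(planted)), function(i) {
    any(abs(annos$peak_mz - observed$mz[i]) < 1e-9 &
          annos$id == planted$id[i] & annos$adduct == planted$adduct[i])
  }, logical(1))
  expect_true(all(hit))
})
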