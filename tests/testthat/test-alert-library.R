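test_that("alert CSV round-trips and validates records", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("alert_id,smarts,description",
               "a1,c1ccccc1N,aromatic amine-ish",
               "a2,[OX2H]c1ccccc1,phenol"), f)
  lib <- readAlertLibrary(f)
  expect_s4_class(lib, "AlertLibrary")
  expect_length(lib, 2)
  expect_identical(alertIds(lib), c("a1", "a2"))

  # malformed SMARTS is reported by the offending alert_id
  writeLines(c("alert_id,smarts,description",
               "good,c1ccccc1N,fine",
               "bad,C(,broken"), f)
  expect_error(readAlertLibrary(f), "bad")

  # header-only file: empty library with a warning
  writeLines("alert_id,smarts,description", f)
  expect_warning(lib0 <- readAlertLibrary(f), "empty")
  expect_length(lib0, 0)

  # missing required column is a format error
  writeLines(c("alert_id,description", "a,desc"), f)
  expect_error(readAlertLibrary(f), "smarts")
})

test_that("duplicate alert ids are rejected", {
  df <- data.frame(alert_id = c("x", "x"), smarts = c("C", "N"),
                   description = c("a", "b"))
  expect_error(AlertLibrary(df, checkSmarts = FALSE), "duplicate")
})

test_that("builtin library compiles, has unique ids and the N-benzene family", {
  lib <- builtinAlerts()
  expect_true(all(validSmarts(alertSmarts(lib))))
  expect_false(anyDuplicated(alertIds(lib)) > 0)
  expect_true(all(c("nb_any", "nb_two_nh", "nb_one_nh", "nb_no_nh",
                    "amine_any", "benzene") %in% alertIds(lib)))
})

test_that("builtin patterns trace correctly on aniline, toluene, benzene", {
  lib <- builtinAlerts()
  screen <- screenDrugs(toyDrugs()[1:3, ], lib)
  m <- matchMatrix(screen)

  # aniline: N-benzene(any) and the two-N-H (primary) variant
  expect_true(m["aniline", "nb_any"])
  expect_true(m["aniline", "nb_two_nh"])
  expect_false(m["aniline", "nb_one_nh"])
  expect_false(m["aniline", "nb_no_nh"])

  # toluene (the paired no-alert control): no N-benzene variant
  expect_false(any(m["toluene", c("nb_any", "nb_two_nh", "nb_one_nh",
                                  "nb_no_nh")]))

  # benzene: only the decomposed benzene pattern among the builtins
  expect_true(m["benzene", "benzene"])
  expect_false(any(m["benzene", setdiff(colnames(m), "benzene")]))
})

test_that("N-H variants are mutually exclusive per nitrogen and imply the any-variant", {
  lib <- builtinAlerts()
  panel <- c("Nc1ccccc1", "CNc1ccccc1", "CN(C)c1ccccc1",
             "Nc1ccc(C)cc1", "CC(=O)Nc1ccccc1", "c1ccc(Nc2ccccc2)cc1",
             "CCN(CC)c1ccccc1", "Nc1ccc(N(C)C)cc1", "[O-][N+](=O)c1ccccc1")
  cls <- classifyAromaticAmine(panel)
  for (i in seq_along(panel)) {
    counts <- cls$n_h_counts[[i]]
    # per nitrogen: exactly one of the three classes
    expect_true(all(counts %in% 0:4))
    per_n <- table(cut(pmin(counts, 2), breaks = c(-1, 0, 1, 2)))
    expect_identical(sum(per_n), length(counts))
  }
  # any molecule-level N-H flag implies a match of the any-substitution alert
  drugs <- data.frame(drug_id = paste0("p", seq_along(panel)), name = panel,
                      smiles = panel, daily_dose_mg = 10,
                      label = rep(c("AD_POSITIVE", "AD_NEGATIVE"),
                                  length.out = length(panel)))
  m <- matchMatrix(screenDrugs(drugs, lib))
  flagged <- cls$two_nh | cls$one_nh | cls$no_nh
  expect_identical(unname(m[, "nb_any"]), flagged)
  # and the variant flags match the SMARTS family column-wise
  expect_identical(unname(m[, "nb_two_nh"]), cls$two_nh)
  expect_identical(unname(m[, "nb_no_nh"]), cls$no_nh)
})

test_that("library subsetting and SMARTS export work", {
  lib <- builtinAlerts()
  sub <- lib[c("nb_any", "benzene")]
  expect_length(sub, 2)
  expect_error(lib["no_such_alert"], "unknown")
  f <- withr::local_tempfile(fileext = ".smarts")
  exportSmartsFile(sub, f)
  lines <- readLines(f)
  expect_length(lines, 2)
  expect_match(lines[1], "^nb_any\t")
})
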