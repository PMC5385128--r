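test_that("five-sites predictions reproduce the published panel values", {
  expect_equal(predict_lambda_max("SHYTA"), 560)  # giraffe-type
  expect_equal(predict_lambda_max("AHYTA"), 553)  # cow/okapi-type
  expect_equal(predict_lambda_max(c("A", "H", "Y", "T", "A")), 553)
  expect_equal(predict_lambda_max("AYFAS"), 487)  # all five shifts applied
  bad <- predict_lambda_max("ZHYTA")
  expect_true(is.na(bad))
  expect_equal(attr(bad, "unavailable_sites"), 180L)
  expect_error(predict_lambda_max("SHYT"), "five residues")
})

test_that("additivity holds exhaustively over all 32 genotypes", {
  alleles <- list(c("S", "A"), c("H", "Y"), c("Y", "F"), c("T", "A"), c("A", "S"))
  shifts <- list(c(S = 0, A = 7), c(H = 0, Y = 28), c(Y = 0, F = 7),
                 c(T = 0, A = 15), c(A = 0, S = 16))
  grid <- expand.grid(alleles, stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 32L)
  for (r in seq_len(nrow(grid))) {
    g <- unlist(grid[r, ])
    brute <- 560 - sum(vapply(1:5, function(i) shifts[[i]][[g[i]]], numeric(1)))
    expect_equal(predict_lambda_max(g), brute)
  }
  preds <- apply(grid, 1, predict_lambda_max)
  expect_true(all(preds >= 487 & preds <= 560))
  # pairwise differences decompose into per-site shift differences
  d <- predict_lambda_max("SHYTA") - predict_lambda_max("AHYAA")
  expect_equal(d, 7 + 15)
  # applying a substitution and its reverse restores the prediction
  expect_equal(predict_lambda_max("SHYTA"),
               predict_lambda_max(c("S", "H", "Y", "T", "A")))
  expect_equal(predict_lambda_max("AHYTA") + 7, predict_lambda_max("SHYTA"))
})

test_that("genotype extraction is alignment-mediated and indel-robust", {
  ref <- codonsel:::bundled_reference()
  # identity: the reference's own genotype
  self <- extract_genotype(ref)
  expect_identical(self$genotype, "SHYTA")
  expect_identical(self$site233, "S")
  expect_equal(self$lambda_max, 560)
  # a single S180A substitution drops the prediction by 7 nm
  mut <- ref
  substr(mut, 180, 180) <- "A"
  g <- extract_genotype(mut)
  expect_identical(g$genotype, "AHYTA")
  expect_equal(g$lambda_max, self$lambda_max - 7)
  # an N-terminal truncation shifts coordinates; mapping must still work
  trunc <- substr(ref, 21, nchar(ref))
  g2 <- extract_genotype(trunc)
  expect_identical(g2$genotype, "SHYTA")
  # a deletion spanning site 285 makes the site missing and the prediction unavailable
  del <- paste0(substr(ref, 1, 282), substr(ref, 290, nchar(ref)))
  g3 <- extract_genotype(del)
  expect_true(is.na(g3$lambda_max))
  expect_true(grepl("-", g3$genotype, fixed = TRUE))
  expect_error(extract_genotype("MKV", reference = "MKV"), "too short")
})

test_that("the genotype table mirrors a species panel", {
  ref <- codonsel:::bundled_reference()
  a180 <- ref; substr(a180, 180, 180) <- "A"
  f277 <- ref; substr(f277, 277, 277) <- "F"
  panel <- c(giraffe = ref, okapi = a180, cow = a180, seal = f277)
  tb <- genotype_table(panel, experimental = c(cow = 555))
  expect_equal(tb$lambda_pred, c(560, 553, 553, 553))
  expect_equal(tb$genotype, c("SHYTA", "AHYTA", "AHYTA", "SHFTA"))
  expect_equal(tb$lambda_exp[tb$species == "cow"], 555)
  # empty panel: empty frame with the full set of columns
  empty <- genotype_table(character(0))
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("species", "genotype", "lambda_pred") %in% names(empty)))
  # duplicate ids kept with a warning
  expect_warning(dup <- genotype_table(c(x = ref, x = ref)), "duplicated")
  expect_equal(nrow(dup), 2L)
  # non-canonical residue yields an unavailable row, not an error
  weird <- ref; substr(weird, 285, 285) <- "W"
  tb2 <- genotype_table(c(ok = ref, odd = weird))
  expect_true(is.na(tb2$lambda_pred[2]))
  expect_match(tb2$note[2], "unavailable")
})
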