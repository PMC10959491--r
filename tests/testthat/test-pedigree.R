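test_that("pedigree construction sorts parents before offspring and validates", {
  # child listed first is reordered
  ped <- pedigree(c("O", "P1", "P2"), c("P1", NA, NA), c("P2", NA, NA))
  expect_lt(which(ped$id == "P1"), which(ped$id == "O"))
  expect_lt(which(ped$id == "P2"), which(ped$id == "O"))

  # founders only: any order valid, all retained
  expect_equal(sort(pedigree(c("a", "b", "c"))$id), c("a", "b", "c"))

  expect_error(pedigree(c("A", "A"), c(NA, NA), c(NA, NA)), "duplicate")
  expect_error(pedigree("A", "A", NA), "own parent")
  expect_error(pedigree(c("A", "B"), c("B", "A"), c(NA, NA)), "cycle")
  expect_error(pedigree("A", "X", NA), "not present")
  # missing parents auto-inserted as founders when allowed
  ped2 <- pedigree("A", "X", "Y", strict_parents = FALSE)
  expect_setequal(ped2$id, c("A", "X", "Y"))
  expect_true(all(is.na(ped2$sire[ped2$id %in% c("X", "Y")])))
  # subspecies labels only on founders
  expect_error(pedigree(c("P", "O"), c(NA, "P"), c(NA, NA),
                        subspecies = c("SAB", "SAB"), strict_parents = FALSE),
               "non-founder")
})

test_that("tabular-method relationship matrix matches textbook cases", {
  expect_equal(amatrix(pedigree(c("a", "b"))), diag(2),
               ignore_attr = TRUE)

  ped <- pedigree(c("P1", "P2", "O"), c(NA, NA, "P1"), c(NA, NA, "P2"))
  A <- amatrix(ped)
  expect_equal(A["O", "P1"], 0.5)
  expect_equal(A["O", "P2"], 0.5)
  expect_equal(A["O", "O"], 1)

  # full sibs X, Y mated; offspring Z is inbred with F = 0.25
  ped <- pedigree(c("P1", "P2", "X", "Y", "Z"),
                  c(NA, NA, "P1", "P1", "X"),
                  c(NA, NA, "P2", "P2", "Y"))
  A <- amatrix(ped)
  expect_equal(A["X", "Y"], 0.5)
  expect_equal(A["Z", "Z"], 1.25)
  expect_equal(A, 2 * kinship_oracle(ped), ignore_attr = TRUE)
})

test_that("relationship matrix equals twice the kinship oracle on random pedigrees", {
  set.seed(42)
  for (rep in 1:20) {
    ped <- random_pedigree(60)
    A <- amatrix(ped)
    expect_lt(max(abs(A - 2 * kinship_oracle(ped))), 1e-12)
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
    expect_true(all(diag(A) >= 1 & diag(A) < 2))
    expect_true(all(A >= 0))
  }
})

test_that("sparse inverse agrees with the dense relationship matrix", {
  set.seed(7)
  for (rep in 1:5) {
    ped <- random_pedigree(40)
    A <- amatrix(ped)
    Ainv <- as.matrix(ainverse(ped))
    expect_lt(max(abs(A %*% Ainv - diag(nrow(A)))), 1e-9)
  }
})

test_that("inbreeding coefficients are the diagonal excess and validated", {
  expect_equal(unname(inbreeding(diag(3))), c(0, 0, 0))
  A <- matrix(c(1.25, 0, 0, 1), 2, 2, dimnames = list(c("z", "w"), c("z", "w")))
  expect_equal(inbreeding(A), c(z = 0.25, w = 0))
  expect_error(inbreeding(diag(2) * 0.9), "outside")
  expect_error(inbreeding(diag(2) * 2.1), "outside")
})

test_that("subspecies fractions average parents and classify hybrids at 85%", {
  ped <- pedigree(c("S", "K", "F1", "BC"),
                  c(NA, NA, "S", "S"),
                  c(NA, NA, "K", "F1"),
                  subspecies = c("SAB", "KR", NA, NA))
  sf <- subspecies_fractions(ped)
  expect_equal(sf$fractions["S", ], c(KR = 0, SAB = 1))
  expect_equal(sf$class[["S"]], "SAB")
  expect_equal(sf$fractions["F1", ], c(KR = 0.5, SAB = 0.5))
  expect_equal(sf$class[["F1"]], "hybrid")
  expect_equal(sf$fractions["BC", ], c(KR = 0.25, SAB = 0.75))
  expect_equal(sf$class[["BC"]], "hybrid")  # 0.75 < 0.85
  expect_equal(unname(rowSums(sf$fractions)), rep(1, 4))

  ped_bad <- pedigree(c("S", "K"), subspecies = c("SAB", NA))
  expect_error(subspecies_fractions(ped_bad), "without subspecies")
})

test_that("pedigree CSV round trip preserves structure", {
  ped <- pedigree(c("P1", "P2", "O"), c(NA, NA, "P1"), c(NA, NA, "P2"),
                  subspecies = c("SAB", "ZB", NA), cohort = c(0L, 0L, 1L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pedigree_csv(ped, path)
  ped2 <- read_pedigree_csv(path)
  expect_equal(as.data.frame(ped), as.data.frame(ped2))
})
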