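test_that("FASTA reading parses the first record and rejects bad codes", {
  fa <- system.file("extdata", "asyn.fasta", package = "saltsyn")
  s <- read_fasta(fa)
  expect_s3_class(s, "protein_sequence")
  expect_length(s, 140)

  tmp <- tempfile(fileext = ".fa")
  writeLines(c(">x", "MDV"), tmp)
  expect_equal(paste(read_fasta(tmp), collapse = ""), "MDV")

  writeLines(c(">x", "MDZ"), tmp)
  expect_error(read_fasta(tmp), "invalid")

  writeLines(character(0), tmp)
  expect_error(read_fasta(tmp))
})

test_that("titratable site enumeration matches the sequence chemistry", {
  s <- asyn_sequence()
  sites <- titratable_sites(s)
  # 24 acidic side chains (D + E) plus the free C-terminus: 25 acidic groups
  expect_equal(sum(sites$kind == "acid" & sites$residue != "Y"), 25)
  expect_true(all(sites$charge_deprotonated[sites$kind == "acid"] == -1))
  expect_true(all(sites$charge_protonated[sites$kind == "base"] == 1))

  ggg <- protein_sequence("GGG")
  expect_equal(nrow(titratable_sites(ggg)), 2)  # termini only
  ggg0 <- protein_sequence("GGG", has_free_nterm = FALSE,
                           has_free_cterm = FALSE)
  expect_equal(nrow(titratable_sites(ggg0)), 0)
})

test_that("site mean charge follows Henderson-Hasselbalch", {
  expect_equal(site_mean_charge("acid", 4.0, 4.0), -0.5)
  expect_equal(site_mean_charge("base", 10.4, 2.0), 1.0, tolerance = 1e-6)
  # direct evaluation: acid pKa 4.0 at pH 5.5
  expect_equal(site_mean_charge("acid", 4.0, 5.5),
               -1 / (1 + 10^(-1.5)))
  expect_equal(round(site_mean_charge("acid", 4.0, 5.5), 4), -0.9693)
})

test_that("net charge is negative at pH 5.5 and monotone decreasing", {
  s <- asyn_sequence()
  expect_lt(net_charge(s, 5.5), 0)
  expect_lt(net_charge(asyn_ctail(), 5.5), 0)
  grid <- seq(1, 13, by = 0.25)
  q <- net_charge(s, grid)
  expect_true(all(diff(q) < 0))
})

test_that("isoelectric point is the unique zero of the charge curve", {
  s <- asyn_sequence()
  pi_hat <- isoelectric_point(s)
  expect_lt(abs(net_charge(s, pi_hat)), 1e-6)
  expect_equal(pi_hat, 4.7, tolerance = 0.2 / 4.7)

  ggg <- protein_sequence("GGG")
  pk <- default_pka_set(); pk["Nterm"] <- 9.0; pk["Cterm"] <- 3.0
  expect_equal(isoelectric_point(ggg, pk), 6.0, tolerance = 1e-3)

  polyE <- protein_sequence("EEEEE", has_free_nterm = FALSE,
                            has_free_cterm = FALSE)
  expect_error(isoelectric_point(polyE), "undefined pI")
})

test_that("regional charges reflect the asymmetric charge distribution", {
  s <- asyn_sequence()
  cp <- charge_profile(s, 5.5)
  expect_gt(cp$region_charges[["nterm"]], 0)    # residues 1-60
  expect_lt(cp$region_charges[["ctail"]], 0)    # residues 101-140
  # the central region 61-95 is essentially uncharged: only E61, K80 and
  # E83 titrate there and their mean charges nearly cancel
  sites <- titratable_sites(s)
  side <- sites$position >= 61 & sites$position <= 95
  expect_equal(sort(sites$position[side]), c(61, 80, 83))
  expect_lt(abs(cp$region_charges[["nac"]]), 1)
  expect_equal(cp$net_charge, sum(cp$sites$charge))
})

test_that("charge table writes a TSV with region columns", {
  s <- asyn_ctail()
  f <- tempfile(fileext = ".tsv")
  tab <- charge_table(s, pH_grid = c(4, 5.5, 7), file = f)
  back <- read.delim(f)
  expect_equal(nrow(back), 3)
  expect_true(all(c("pH", "net_charge") %in% names(back)))
  expect_equal(back$net_charge, tab$net_charge, tolerance = 1e-9)
})

test_that("pKa sets load from key-value files and are validated", {
  f <- tempfile()
  writeLines(c("D: 3.9", "E = 4.3", "# comment"), f)
  pk <- read_pka_set(f)
  expect_equal(pk[["D"]], 3.9)
  expect_equal(pk[["E"]], 4.3)
  expect_equal(pk[["K"]], default_pka_set()[["K"]])
  writeLines("Q: 5.0", f)
  expect_error(read_pka_set(f), "unknown")
  writeLines("D: 15", f)
  expect_error(read_pka_set(f), "out of")
})
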