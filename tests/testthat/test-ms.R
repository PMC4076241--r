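test_that("spectrum reader handles the two-column dialect, sorting and errors", {
  f <- withr::local_tempfile(fileext = ".msd")
  writeLines(c("# comment", "1500 0", "1500.1 10", "1500.2 0"), f)
  s <- read_ms(f)
  expect_length(s$mz, 3L)
  writeLines(c("1500.2 1", "1500.0 3", "1500.1 2"), f)
  s <- read_ms(f)
  expect_false(is.unsorted(s$mz))
  expect_equal(s$intensity, c(3, 2, 1))
  writeLines(c("1500 1", "not numeric"), f)
  expect_error(read_ms(f), "line 2")
  writeLines(character(0), f)
  expect_error(read_ms(f), "no data rows")
})

test_that("written spectra read back identically", {
  truth <- synth_spectrum(list(c(Hex = 5, HexNAc = 2)), seed = 3)
  f <- withr::local_tempfile(fileext = ".msd")
  write_ms(truth$spectrum, f)
  s2 <- read_ms(f)
  expect_equal(s2$mz, truth$spectrum$mz, tolerance = 1e-6)
  expect_equal(s2$intensity, truth$spectrum$intensity, tolerance = 1e-6)
})

test_that("peak processing recovers five known Gaussian peaks", {
  comps <- list(c(Hex = 5, HexNAc = 2), c(Hex = 5, HexNAc = 4),
                c(Hex = 5, HexNAc = 4, dHex = 1),
                c(Hex = 5, HexNAc = 4, NeuAc = 1),
                c(Hex = 5, HexNAc = 4, dHex = 1, NeuAc = 2))
  syn <- synth_spectrum(comps, heights = c(80, 60, 50, 40, 30),
                        noise_sigma = 2, seed = 9) # SNR ~ 20 on the base peak
  pl <- ms_process(syn$spectrum)
  expect_equal(nrow(pl), 5L)
  matched <- vapply(syn$truth$mz, function(mz) min(abs(pl$centroid - mz)), 0)
  expect_true(all(matched < 0.1))
  expect_true(all(pl$fwhm > 0.2 & pl$fwhm < 0.6)) # sigma 0.15 -> FWHM 0.353
})

test_that("an all-zero or flat spectrum yields an empty peak list", {
  s <- glyconet:::new_spectrum(seq(1500, 1600, by = 0.05),
                               rep(0, length(seq(1500, 1600, by = 0.05))))
  expect_equal(nrow(ms_process(s)), 0L)
})

test_that("processing is invariant to intensity scaling and baseline offset", {
  syn <- synth_spectrum(list(c(Hex = 5, HexNAc = 2), c(Hex = 6, HexNAc = 5)),
                        heights = 50, noise_sigma = 1, seed = 4)
  base <- ms_process(syn$spectrum)
  scaled <- glyconet:::new_spectrum(syn$spectrum$mz, syn$spectrum$intensity * 1000)
  out_s <- ms_process(scaled)
  expect_equal(out_s$centroid, base$centroid, tolerance = 1e-8)
  expect_equal(out_s$height, base$height, tolerance = 1e-6)
  offset <- glyconet:::new_spectrum(syn$spectrum$mz, syn$spectrum$intensity + 25)
  out_o <- ms_process(offset)
  expect_equal(nrow(out_o), nrow(base))
  expect_equal(out_o$centroid, base$centroid, tolerance = 0.05)
})

test_that("composition annotation matches the independent mass oracle", {
  target <- c(Hex = 5, HexNAc = 2)
  mz <- oracle_perm_sodiated_mz(target)
  # the package's own mass for the same composition agrees with the oracle
  expect_equal(composition_mz(target), mz, tolerance = 1e-4)
  ann <- annotate_compositions(mz, tol_ppm = 20)
  hits <- ann[[1]]$candidates
  expect_gt(nrow(hits), 0L)
  expect_true(any(hits$Hex == 5 & hits$HexNAc == 2 & hits$dHex == 0 & hits$NeuAc == 0))
})

test_that("the tri-antennary bisected fucosylated composition annotates its peak", {
  target <- c(Hex = 6, HexNAc = 6, dHex = 1)
  mz <- oracle_perm_sodiated_mz(target) # ~2938.5, the published ~2937.9 peak
  ann <- annotate_compositions(mz, tol_ppm = 20)
  hits <- ann[[1]]$candidates
  expect_true(any(hits$Hex == 6 & hits$HexNAc == 6 & hits$dHex == 1 & hits$NeuAc == 0))
})

test_that("zero tolerance keeps only exact-mass matches", {
  mz <- composition_mz(c(Hex = 3, HexNAc = 2))
  ann0 <- annotate_compositions(mz, tol_ppm = 0)
  expect_true(all(ann0[[1]]$candidates$ppm == 0))
  expect_true(nrow(ann0[[1]]$candidates) >= 1L)
})

test_that("annotation equals brute-force enumeration over the bounded lattice", {
  bounds <- c(Hex = 4, HexNAc = 3, dHex = 1, NeuAc = 1)
  centroids <- c(1580, 1835.93, 2000)
  ann <- annotate_compositions(centroids, tol_ppm = 50, bounds = bounds)
  for (i in seq_along(centroids)) {
    brute <- character(0)
    for (h in 0:bounds[["Hex"]]) for (n in 0:bounds[["HexNAc"]])
      for (d in 0:bounds[["dHex"]]) for (s in 0:bounds[["NeuAc"]]) {
        if (h + n + d + s == 0) next
        cc <- c(Hex = h, HexNAc = n, dHex = d, NeuAc = s)
        m <- oracle_perm_sodiated_mz(cc)
        if (abs(m - centroids[i]) / centroids[i] * 1e6 <= 50) {
          brute <- c(brute, paste(h, n, d, s))
        }
      }
    got <- with(ann[[i]]$candidates, paste(Hex, HexNAc, dHex, NeuAc))
    expect_setequal(got, brute)
    expect_true(all(ann[[i]]$candidates$ppm <= 50))
  }
})

test_that("the generator's truth table is seed-stable while noise differs", {
  comps <- list(c(Hex = 5, HexNAc = 2), c(Hex = 5, HexNAc = 4))
  a <- synth_spectrum(comps, seed = 1)
  b <- synth_spectrum(comps, seed = 2)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$spectrum$intensity, b$spectrum$intensity))
  # noiseless, baseline-free generation recovers centroids to grid resolution
  clean <- synth_spectrum(comps, noise_sigma = 0, baseline = c(0, 0), seed = 1)
  pl <- ms_process(clean$spectrum)
  expect_equal(nrow(pl), 2L)
  expect_true(all(abs(pl$centroid - clean$truth$mz) < 0.05))
})
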