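test_that("microsatellite tables parse allele pairs, missing calls, and locus sets", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tM1\tM2",
               "S1\t104/110\t./.",
               "S2\t110/104\t200/200",
               "S3\t104/104\t202/200"), path)
  g <- read_microsat_table(path)
  expect_equal(dim(g), c(3L, 2L))
  expect_equal(unname(c(g$a1["S1", "M1"], g$a2["S1", "M1"])), c(104L, 110L))
  expect_true(is.na(g$a1["S1", "M2"]) && is.na(g$a2["S1", "M2"]))
  # unordered: "110/104" and "104/110" parse to equal genotypes
  expect_equal(g$a1["S2", "M1"], g$a1["S1", "M1"])
  expect_equal(g$a2["S2", "M1"], g$a2["S1", "M1"])
  expect_equal(msat_allele_catalog(g)$M2, c(200L, 202L))

  # one locus column per marker
  wide <- data.frame(sample_id = "S1",
                     matrix("100/102", 1, 19,
                            dimnames = list(NULL, sprintf("MK%02d", 1:19))),
                     check.names = FALSE)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(wide, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_microsat_table(p2)$loci), 19L)
})

test_that("malformed tables are rejected with the offending row named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tM1", "S1\t104"), path)
  expect_error(read_microsat_table(path), "malformed.*S1")
  writeLines(c("sample_id\tM1", "S1\t104/ab"), path)
  expect_error(read_microsat_table(path), "non-integer.*S1")
  writeLines(c("sample_id\tM1", "S1\t104/106", "S1\t104/106"), path)
  expect_error(read_microsat_table(path), "duplicate sample id")
  expect_error(msat_geno("S1", data.frame(id = "M1", chrom = NA, pos_bp = NA),
                         matrix(104L), matrix(NA_integer_)),
               "half-missing")
})

test_that("microsatellite table writing round-trips", {
  g <- msat_geno(c("A", "B"),
                 data.frame(id = c("M1", "M2"), chrom = NA, pos_bp = NA),
                 a1 = matrix(c(104L, NA, 200L, 202L), 2),
                 a2 = matrix(c(110L, NA, 204L, 202L), 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_microsat_table(g, path)
  g2 <- read_microsat_table(path)
  expect_equal(g2$a1, g$a1)
  expect_equal(g2$a2, g$a2)
})

test_that("the microsatellite VCF dialect round-trips coded genotypes exactly", {
  loci <- data.frame(id = c("M1", "M2"), chrom = c("1", "1"),
                     pos_bp = c(1000L, 5000L))
  g <- msat_geno(c("A", "B", "C"), loci,
                 a1 = matrix(c(110L, 104L, NA, 200L, 204L, 200L), 3),
                 a2 = matrix(c(104L, 120L, NA, 202L, 204L, 200L), 3))
  maps <- list(M1 = c(`104` = 0L, `110` = 1L, `120` = 2L),
               M2 = c(`200` = 0L, `202` = 1L, `204` = 2L))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_msat_vcf(g, maps, path)
  lines <- readLines(path)
  rec <- strsplit(grep("\tM1\t", lines, value = TRUE), "\t")[[1]]
  expect_equal(rec[4], "N")
  expect_equal(rec[5], "<A1>,<A2>")                 # 1 REF + 2 ALT alleles
  expect_equal(rec[8], "ALEN=104,110,120")
  expect_equal(rec[10], "0/1")                      # (110,104) -> codes 0/1
  rt <- read_msat_vcf(path)
  expect_equal(rt$geno$a1, g$a1)
  expect_equal(rt$geno$a2, g$a2)
  expect_equal(rt$code_maps$M1, maps$M1)

  # independent parser agrees on the dialect
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  expect_equal(unname(v@fix[, "ID"]), c("M1", "M2"))
  expect_equal(unname(v@gt[1, -1]), c("0/1", "0/2", NA))
})

test_that("msat VCF writing validates positions and codes", {
  loci <- data.frame(id = c("M1", "M2"), chrom = "1", pos_bp = c(5000L, 1000L))
  g <- msat_geno("A", loci, matrix(c(104L, 200L), 1), matrix(c(104L, 200L), 1))
  maps <- list(M1 = c(`104` = 0L), M2 = c(`200` = 0L))
  path <- withr::local_tempfile(fileext = ".vcf")
  expect_error(write_msat_vcf(g, maps, path), "unsorted")
  # unknown INFO key on read
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "A"), collapse = "\t"),
               paste(c("1", "1000", "M1", "N", ".", ".", "PASS",
                       "ALEN=104;FOO=1", "GT", "0/0"), collapse = "\t")), path)
  expect_error(read_msat_vcf(path), "unknown INFO key 'FOO'")
})

test_that("SNP VCFs round-trip with phase", {
  map <- data.frame(snp_id = c("s1", "s2", "s3"), chrom = "2",
                    pos = c(100L, 200L, 300L))
  x <- snp_matrix(c("A", "B"), map,
                  geno = rbind(c(0L, 1L, 2L), c(1L, NA, 0L)),
                  hap1 = rbind(c(0L, 1L, 1L), c(0L, NA, 0L)),
                  hap2 = rbind(c(0L, 0L, 1L), c(1L, NA, 0L)))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_snp_vcf(x, path)
  rt <- read_snp_vcf(path)
  expect_equal(rt$geno, x$geno)
  expect_equal(rt$hap1, x$hap1)
  expect_equal(rt$map, x$map)
  expect_error(snp_matrix("A", map[c(2, 1, 3), ], matrix(0L, 1, 3)),
               "not sorted")
})

test_that("pedigrees load, validate cycles, and expose parent-offspring pairs", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A 0 0", "B 0 0", "C A B"), path)
  ped <- read_pedigree(path)
  pairs <- ped_pairs(ped)
  expect_equal(nrow(pairs), 2L)
  expect_setequal(pairs$parent, c("A", "B"))
  expect_equal(unique(pairs$offspring), "C")

  writeLines(c("A B 0", "B A 0"), path)
  expect_error(read_pedigree(path), "cycle")

  # unknown parent auto-added as founder, with warning
  writeLines(c("C A B", "A 0 0"), path)
  expect_warning(ped2 <- read_pedigree(path), "added as founders")
  expect_true("B" %in% ped2$id)
  expect_true(match("B", ped2$id) < match("C", ped2$id))  # topological order

  # n recorded links -> n extractable pairs (e.g. 1450)
  n_off <- 725L
  big <- data.frame(id = c("P1", "P2", sprintf("O%03d", seq_len(n_off))),
                    sire = c(NA, NA, rep("P1", n_off)),
                    dam = c(NA, NA, rep("P2", n_off)))
  expect_equal(nrow(ped_pairs(as_pedigree(big))), 1450L)
})

test_that("pedigree round-trip through the three-column text format is lossless", {
  ped <- as_pedigree(data.frame(id = c("A", "B", "C", "D"),
                                sire = c(NA, NA, "A", "A"),
                                dam = c(NA, NA, "B", NA)))
  path <- withr::local_tempfile(fileext = ".txt")
  write_pedigree(ped, path)
  rt <- read_pedigree(path)
  expect_equal(as.data.frame(rt), as.data.frame(ped))
})
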