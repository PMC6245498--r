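test_that("tabular APC reading handles classes, errors, and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tS1\tS2", "s1\tA\tG", "s2\tA\tH", "s3\tB\tG"), tmp)
  apc <- read_apc(tmp, format = "tsv")
  expect_s3_class(apc, "apc_table")
  expect_equal(dim(apc), c(3L, 2L))
  expect_null(apc$class_labels)

  # class column is pulled out of the attributes
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tcls\tS1\tS2", "s1\tC1\tA\tG", "s2\tC2\tA\tH",
               "s3\tC1\tB\tG"), tmp2)
  apc2 <- read_apc(tmp2, class_source = "cls")
  expect_equal(apc2$site_labels, c("S1", "S2"))
  expect_equal(apc2$class_labels, c("C1", "C2", "C1"))
  expect_error(read_apc(tmp2, class_source = "nope"), "unknown class")

  # duplicate sequence IDs rejected
  tmp3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tS1\tS2", "s1\tA\tG", "s1\tB\tH"), tmp3)
  expect_error(read_apc(tmp3), "duplicate sequence IDs")

  # TSV round trip is byte-identical
  out <- withr::local_tempfile(fileext = ".tsv")
  write_apc(apc2, out, class_column = "cls")
  expect_identical(readLines(out), readLines(tmp2))
})

test_that("aligned FASTA input with a class map yields a labelled APC", {
  skip_if_not_installed("Biostrings")
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "ACDEF", ">p2", "ACDEG", ">p3", "AKDEF", ">p4",
               "ACDEF"), fa)
  cm <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("p1\tX", "p2\tX", "p3\tY", "p4\tY"), cm)
  apc <- read_apc(fa, format = "aligned-fasta", class_source = cm)
  expect_equal(dim(apc), c(4L, 5L))
  expect_equal(length(apc$class_labels), 4L)
  expect_equal(apc$values[[2]], c("C", "C", "K", "C"))

  # ragged alignment is a format error
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "ACDEF", ">p2", "ACD"), bad)
  expect_error(read_apc(bad, format = "aligned-fasta"), "equal length")
})

test_that("a many-row table with a multi-valued class column loads intact", {
  # mirrors a real APC: 85 sequences, 4 taxonomic classes
  set.seed(42)
  classes <- sample(c("Mammal", "Plant", "Fungi", "Insect"), 85,
                    replace = TRUE)
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(id = sprintf("q%02d", 1:85), taxon = classes,
                   S71 = sample(c("L", "I"), 85, TRUE),
                   S92 = sample(c("L", "V", "A"), 85, TRUE))
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  apc <- read_apc(tmp, format = "csv", class_source = "taxon")
  expect_equal(nrow(apc$values), 85L)
  expect_equal(length(unique(apc$class_labels)), 4L)
})

test_that("property expansion produces 5N mixed-mode attributes", {
  res <- matrix(c("F", "L", "D", "K", "G", "W", "A", "V", "R",
                  "F", "I", "E", "K", "G", "W", "A", "V", "R"),
                nrow = 2, byrow = TRUE)
  apc <- apc_table(as.data.frame(res, stringsAsFactors = FALSE),
                   sequence_ids = c("s1", "s2"),
                   site_labels = as.character(71:79))
  appc <- expand_to_appc(apc)
  expect_equal(ncol(appc$values), 45L)  # 9 sites x 5 properties
  expect_equal(appc$attribute_kinds,
               rep(c("categorical", "categorical", "numeric", "numeric",
                     "numeric"), 9))
  # display label concatenates site and property index; F is aromatic
  expect_true("711" %in% appc$site_labels)
  expect_equal(appc$values[["711"]], c("NonPolar_aromatic",
                                       "NonPolar_aromatic"))
  expect_equal(appc$attr_meta$site[1:5], rep("71", 5))
  expect_equal(appc$attr_meta$property_index[1:5], 1:5)
  # hydropathy of L at the second site
  expect_equal(appc$values[["723"]], c(3.8, 4.5))

  # unknown symbol names the offending cell
  apc$values[[1]][2] <- "Z"
  expect_error(expand_to_appc(apc), "symbol 'Z'.*site '71'")
})

test_that("property round-trip: expanded tuples are residue-consistent", {
  props <- amino_acid_properties()
  apc <- apc_table(data.frame(a = c("A", "W", "K"), b = c("D", "D", "C"),
                              stringsAsFactors = FALSE),
                   sequence_ids = paste0("s", 1:3))
  appc <- expand_to_appc(apc, props)
  for (i in 1:3) {
    for (j in 1:2) {
      sym <- apc$values[[j]][i]
      tuple <- vapply(1:5, function(p) {
        as.character(appc$values[[(j - 1) * 5 + p]][i])
      }, character(1))
      expect_equal(tuple,
                   vapply(props[sym, ], as.character, character(1)),
                   ignore_attr = TRUE)
    }
  }
})

test_that("gap cells expand to missing values excluded from counting", {
  apc <- apc_table(data.frame(a = c("A", "-", "A"), b = c("D", "D", "C"),
                              stringsAsFactors = FALSE),
                   sequence_ids = paste0("s", 1:3))
  appc <- expand_to_appc(apc)
  expect_true(is.na(appc$values[["a1"]][2]))
  disc <- maybe_discretize(appc)
  fm <- build_frequency_matrix(disc$apc)
  # pair (a-polarity, b-polarity): only the 2 complete rows counted
  blk <- fm$counts[grep("^a1=", rownames(fm$counts)),
                   grep("^b1=", colnames(fm$counts)), drop = FALSE]
  expect_equal(sum(blk), 2)
})

test_that("single-row APC expands and survives the address table", {
  apc <- apc_table(data.frame(a = "A", b = "C", stringsAsFactors = FALSE),
                   sequence_ids = "s1")
  appc <- expand_to_appc(apc)
  expect_equal(nrow(appc$values), 1L)
  at <- build_address_table(apc)
  expect_equal(at[["a=A"]]$sequence_id, "s1")
})

test_that("address table maps events to exact cells and answers ARA queries", {
  apc <- toy_apc()
  at <- build_address_table(apc)
  # exhaustive scan of the toy grid
  expect_equal(at[["S1=a"]]$sequence_id, c("s1", "s2"))
  expect_equal(at[["S1=b"]]$sequence_id, c("s3", "s4"))
  expect_equal(lookup_address(at, c("S1", "a"), c("S2", "x")),
               c("s1", "s2"))
  # disjoint supports give an empty hit list
  expect_length(lookup_address(at, c("S1", "a"), c("S2", "y")), 0L)
  # per-attribute occurrence totals equal M
  for (site in apc$site_labels) {
    keys <- grep(paste0("^", site, "="), names(at), value = TRUE)
    expect_equal(sum(vapply(at[keys], nrow, integer(1))), 4L)
  }
})

test_that("address-table counts match column value counts on random tables", {
  set.seed(7)
  for (rep in 1:5) {
    apc <- random_apc(sample(5:30, 1), sample(2:4, 1))
    at <- build_address_table(apc)
    for (j in seq_along(apc$values)) {
      site <- apc$site_labels[j]
      tab <- table(apc$values[[j]])
      for (val in names(tab)) {
        expect_equal(nrow(at[[paste0(site, "=", val)]]),
                     unname(tab[val]), ignore_attr = TRUE)
      }
    }
  }
})
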