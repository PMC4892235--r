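test_that("name normalization is canonical and idempotent", {
  expect_equal(normalize_name("Canis_lupus"), "Canis lupus")
  expect_equal(normalize_name("  FELIS silvestris "), "Felis silvestris")
  expect_equal(normalize_name("Canis lupus (Linnaeus, 1758)"), "Canis lupus")
  expect_equal(normalize_name("Mus_musculus_2"), "Mus musculus")
  expect_equal(normalize_name("Rodentia"), "Rodentia")
  expect_error(normalize_name("   "), "empty")

  messy <- c("GENUS_species", "a_b_c", " X  y\tz ", "Homo sapiens 1987",
             "'Ailurus fulgens'")
  once <- normalize_name(messy)
  expect_identical(normalize_name(once), once)
})

test_that("reference filtering drops and reports non-reference names", {
  ref <- c("Canis lupus", "Felis catus")
  kept <- suppressMessages(
    filter_to_reference(c("Canis lupus", "Tyrannosaurus rex"), ref))
  expect_equal(as.character(kept), "Canis lupus")
  expect_equal(attr(kept, "excluded"), "Tyrannosaurus rex")
  expect_message(filter_to_reference(c("X y"), ref), "excluding 1")

  sub <- filter_to_reference("Felis catus", ref, quiet = TRUE)
  expect_equal(as.character(sub), "Felis catus")
  expect_length(filter_to_reference(c("A a", "B b"), ref, quiet = TRUE), 0)
})

test_that("lifting species sets to higher levels collapses correctly", {
  tax <- data.frame(
    species = c("Canis lupus", "Canis aureus", "Vulpes vulpes", "Felis catus"),
    genus = c("Canis", "Canis", "Vulpes", "Felis"),
    family = c("Canidae", "Canidae", "Canidae", "Felidae"),
    order = "Carnivora", stringsAsFactors = FALSE)
  expect_equal(lift_to_level(c("Canis lupus", "Canis aureus"), tax, "genus"),
               "Canis")
  expect_equal(lift_to_level(tax$species, tax, "family"),
               c("Canidae", "Felidae"))
  s <- c("Felis catus", "Canis lupus")
  expect_equal(lift_to_level(s, tax, "species"), sort(s))
  for (i in 1:5) {
    s <- sample(tax$species, sample(2:4, 1))
    expect_lte(length(lift_to_level(s, tax, "genus")), length(s))
  }
  expect_warning(lift_to_level("Mus musculus", tax, "genus"), "not in taxonomy")
  expect_error(lift_to_level("Mus musculus", tax, "genus", strict = TRUE),
               "not in taxonomy")
})

test_that("coverage classification uses strict low/high boundaries and is monotone", {
  expect_equal(as.character(classify_coverage(0.17)), "low")
  expect_equal(as.character(classify_coverage(0.25)), "medium")
  expect_equal(as.character(classify_coverage(0.75)), "medium")
  expect_equal(as.character(classify_coverage(0.80)), "high")
  expect_equal(as.character(classify_coverage(c(0, 1))), c("low", "high"))
  expect_error(classify_coverage(1.2), "outside")
  expect_error(classify_coverage(-0.1), "outside")

  grid <- classify_coverage(seq(0, 1, by = 0.01))
  expect_true(all(diff(as.integer(grid)) >= 0))
})

test_that("coverage records carry exact counts, proportions and classes", {
  ref <- sprintf("Taxon %03d", 1:283)
  rec <- coverage(focal_set("Carnivora", "species", ref[1:75], ref))
  expect_equal(rec$n_scored, 75)
  expect_equal(rec$n_total, 283)
  expect_equal(rec$proportion, 75 / 283, tolerance = 1e-12)
  expect_equal(rec$coverage_class, "medium")

  ref2 <- sprintf("Taxon %03d", 1:351)
  expect_equal(coverage(focal_set("Primates", "species",
                                  ref2[1:64], ref2))$coverage_class, "low")
  fam <- sprintf("Fam %02d", 1:21)
  rec3 <- coverage(focal_set("Cetartiodactyla", "family", fam, fam))
  expect_equal(rec3$proportion, 1)
  expect_equal(rec3$coverage_class, "high")

  # set semantics: duplicated scored names change nothing
  dup <- coverage(focal_set("X", "species", c(ref[1:75], ref[1:10]), ref))
  expect_equal(dup$n_scored, 75)

  expect_error(focal_set("X", "species", "Z z", ref), "absent from reference")
})

test_that("taxonomy validation enforces uniqueness and nested mappings", {
  tax <- data.frame(species = c("A a", "A a"), genus = "A",
                    family = "Af", order = "O", stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".csv")
  write.csv(tax, f, row.names = FALSE)
  expect_error(read_taxonomy(f), "duplicate species")

  tax2 <- data.frame(species = c("A a", "A b"), genus = "A",
                     family = c("F1", "F2"), order = "O",
                     stringsAsFactors = FALSE)
  write.csv(tax2, f, row.names = FALSE)
  expect_error(read_taxonomy(f), "multiple families")

  tax3 <- data.frame(species = c("a_a", "B b"), genus = c("A", "B"),
                     family = c("F1", "F2"), order = "O",
                     stringsAsFactors = FALSE)
  write.csv(tax3, f, row.names = FALSE)
  got <- read_taxonomy(f)
  expect_equal(got$species, c("A a", "B b"))
})

test_that("species totals are conserved when orders partition the taxonomy", {
  tr <- simulate_yule(40, seed = 11)
  tax <- two_order_taxonomy(tr)
  per_order <- tapply(tax$species, tax$order, length)
  expect_equal(sum(per_order), nrow(tax))
  expect_equal(length(unique(tax$species)), nrow(tax))
  # every genus in exactly one family, every family in exactly one order
  expect_true(!anyDuplicated(unique(tax[, c("genus", "family")])$genus))
  expect_true(!anyDuplicated(unique(tax[, c("family", "order")])$family))
})

test_that("NEXUS taxon extraction reads TAXLABELS and MATRIX row labels", {
  f1 <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN TAXA;", "DIMENSIONS NTAX=3;",
               "TAXLABELS", "Canis_lupus 'Felis silvestris' Ursus_arctos", ";",
               "END;"), f1)
  expect_equal(nexus_taxa(f1),
               c("Canis lupus", "Felis silvestris", "Ursus arctos"))

  f2 <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "DIMENSIONS NTAX=2 NCHAR=4;",
               "FORMAT DATATYPE=STANDARD MISSING=? GAP=-;",
               "MATRIX", "Canis_lupus 0101", "'Felis catus' 1?10", ";",
               "END;"), f2)
  expect_setequal(nexus_taxa(f2), c("Canis lupus", "Felis catus"))

  f3 <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN TREES;", "END;"), f3)
  expect_error(nexus_taxa(f3), "no taxon names")
})
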