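test_that("annotation tables load, index and respect vocabularies", {
  store <- toy_store(
    features = c("P1\t10\t20\tdomain\tPfam:BRCT", "P1\t427\t427\tptm_site\tPHOS"),
    somatic = "P1\t427\tS\tF\tCOSM1\tbladder\tcarcinoma",
    predictions = "P1\t427\tF\tSIFT\t0.010\tdamaging")
  expect_equal(nrow(features_at(store, "P1", 15)), 1L)
  expect_equal(features_at(store, "P1", 427)$category, "ptm_site")
  expect_equal(somatic_at(store, "P1", 427)$tumor_site, "bladder")
  expect_equal(predictions_for(store, "P1", 427, "F")$method, "SIFT")
  expect_equal(nrow(predictions_for(store, "P1", 427, "Y")), 0L)

  # empty prediction table is a valid degenerate store
  empty <- load_annotation_tables(NULL, NULL, NULL)
  expect_equal(nrow(empty$predictions), 0L)
  expect_equal(nrow(features_at(empty, "P1", 1)), 0L)

  expect_error(toy_store(features = "P1\t1\t2\tnot_a_category\tz"),
               "unknown feature category")
  expect_error(toy_store(predictions = "P1\t1\tA\tNotATool\t0.1\tdamaging"),
               "unknown prediction method")
})

test_that("feature ranges use inclusive ends on both sides", {
  store <- toy_store(features = "P1\t10\t20\tdomain\tPfam:BRCT")
  expect_equal(nrow(features_at(store, "P1", 10)), 1L)
  expect_equal(nrow(features_at(store, "P1", 20)), 1L)
  expect_equal(nrow(features_at(store, "P1", 9)), 0L)
  expect_equal(nrow(features_at(store, "P1", 21)), 0L)
})

test_that("each rule clause fires alone with matching evidence", {
  site <- data.frame(protein_id = "P1", start = 10L, end = 10L,
                     category = "catalytic_site", label = "CAT")
  r <- classify_variant(toy_row(direct = site))
  expect_equal(r$call, "damaging")
  expect_match(r$evidence, "^direct_site:catalytic_site")

  nbr <- data.frame(category = "binding_site", label = "B",
                    neighbor_protein = "P2", neighbor_position = 30L,
                    neighbor_residue = "B:30", distance = 4.5,
                    relation = "interface_partner",
                    sequence_adjacent = FALSE)
  r <- classify_variant(toy_row(neighbor = nbr))
  expect_equal(r$call, "damaging")
  expect_match(r$evidence, "^neighbor_site:binding_site")

  r <- classify_variant(toy_row(interface = TRUE))
  expect_equal(r$call, "damaging")
  expect_match(r$evidence, "^interface:")

  som <- data.frame(sample_id = "COSM1", tumor_site = "bladder",
                    histology = "carcinoma")
  r <- classify_variant(toy_row(somatic = som))
  expect_equal(r$call, "damaging")
  expect_match(r$evidence, "^somatic:COSM1")

  pred <- data.frame(method = c("SIFT", "Polyphen2", "MutationTaster"),
                     score = c(0.01, 0.99, 0.2),
                     call = c("damaging", "damaging", "tolerated"))
  r <- classify_variant(toy_row(predictions = pred))
  expect_equal(r$call, "damaging")
  expect_match(r$evidence, "predictor_majority:2/3")
})

test_that("calls distinguish neutral from no_evidence and obey toggles", {
  pred_tol <- data.frame(method = c("SIFT", "Polyphen2", "MutationTaster"),
                         score = c(0.8, 0.1, 0.1), call = rep("tolerated", 3))
  expect_equal(classify_variant(toy_row(predictions = pred_tol))$call,
               "neutral")
  expect_equal(classify_variant(toy_row())$call, "no_evidence")
  expect_equal(classify_variant(toy_row())$evidence, character(0))

  # ties do not fire the predictor clause; unknown calls do not vote
  tie <- data.frame(method = c("SIFT", "Polyphen2"), score = c(0, 1),
                    call = c("damaging", "tolerated"))
  expect_equal(classify_variant(toy_row(predictions = tie))$call, "neutral")
  unk <- data.frame(method = c("SIFT", "Polyphen2", "LRT"),
                    score = c(0, 1, 1),
                    call = c("damaging", "unknown", "unknown"))
  expect_equal(classify_variant(toy_row(predictions = unk))$call,
               "damaging")

  # disabling every clause leaves no damaging call possible
  off <- rule_config(direct_site = FALSE, neighbor_site = FALSE,
                     interface = FALSE, somatic = FALSE,
                     predictor_majority = FALSE)
  site <- data.frame(protein_id = "P1", start = 10L, end = 10L,
                     category = "catalytic_site", label = "CAT")
  pred_dam <- data.frame(method = "SIFT", score = 0, call = "damaging")
  r <- classify_variant(toy_row(direct = site, interface = TRUE,
                                predictions = pred_dam), off)
  expect_equal(r$call, "neutral")
  expect_equal(r$evidence, character(0))
})

test_that("sequence-adjacent neighbor sites are discounted by default", {
  nbr <- data.frame(category = "ptm_site", label = "P",
                    neighbor_protein = "P1", neighbor_position = 11L,
                    neighbor_residue = "A:11", distance = 3.8,
                    relation = "intra_chain", sequence_adjacent = TRUE)
  expect_equal(classify_variant(toy_row(neighbor = nbr))$call,
               "no_evidence")
  allow <- rule_config(count_sequence_adjacent = TRUE)
  expect_equal(classify_variant(toy_row(neighbor = nbr), allow)$call,
               "damaging")
})

test_that("annotate_variant composes geometry, maps and the store end-to-end", {
  # chain A residue 5 contacts chain B residue 30 at 4.5 A; the partner
  # position carries a binding site on protein P2
  s <- placed_structure(data.frame(
    chain = c("A", "A", "B"), resno = c(5, 6, 30),
    aa3 = c("MET", "LYS", "TRP"),
    x = c(0, 3.8, 0), y = c(0, 0, 0), z = c(0, 0, 4.5)),
    chain_protein = c(A = "P1", B = "P2"))
  catalog <- read_isoform_catalog(write_lines(c(
    "gene_id\tprotein_id\tprincipal\tsequence",
    "G1\tP1\t1\tMK", "G2\tP2\t1\tW")))
  store <- toy_store(features = "P2\t1\t1\tbinding_site\tPOCKET")
  ctx <- build_structure_context(list(s), catalog)
  rows <- annotate_variant(list(protein_id = "P1", position = 1L,
                                ref_aa = "M", alt_aa = "V"),
                           store, ctx)
  expect_length(rows, 1L)
  row <- rows[[1]]
  expect_equal(row$mapped_residue, "5")
  expect_true(row$interface_flag)
  expect_equal(nrow(row$neighbor_features), 1L)
  expect_equal(row$neighbor_features$category, "binding_site")
  expect_equal(row$neighbor_features$relation, "interface_partner")
  expect_equal(row$neighbor_features$distance, 4.5)
  expect_equal(row$neighbor_features$neighbor_position, 1L)
  expect_equal(row$call, "damaging")
  # oracle: manual composition of spatial_neighbors + features_at
  nb <- spatial_neighbors(s, "A", 5, cutoff = 5)
  partner <- nb[nb$relation == "interface_partner", ]
  expect_equal(features_at(store, "P2", 1)$label,
               row$neighbor_features$label)
  expect_equal(partner$distance, row$neighbor_features$distance)
})

test_that("variants without structure coverage get one structure-free row", {
  store <- toy_store(features = "P9\t3\t3\tcatalytic_site\tCAT")
  rows <- annotate_variant(list(protein_id = "P9", position = 3L,
                                ref_aa = "A", alt_aa = "V"), store, list())
  expect_length(rows, 1L)
  expect_true(is.na(rows[[1]]$structure_id))
  expect_equal(rows[[1]]$direct_features$category, "catalytic_site")
  expect_equal(rows[[1]]$call, "damaging")
})

test_that("catalog reference mismatches suppress structural annotation", {
  s <- placed_structure(data.frame(chain = "A", resno = 1, aa3 = "MET",
                                   x = 0, y = 0, z = 0),
                        chain_protein = c(A = "P1"))
  catalog <- read_isoform_catalog(write_lines(c(
    "gene_id\tprotein_id\tprincipal\tsequence", "G1\tP1\t1\tM")))
  ctx <- build_structure_context(list(s), catalog)
  rows <- annotate_variant(list(protein_id = "P1", position = 1L,
                                ref_aa = "W", alt_aa = "V"),
                           load_annotation_tables(), ctx,
                           catalog = catalog)
  expect_length(rows, 1L)
  expect_true("ref_mismatch" %in% rows[[1]]$flags)
  expect_true(is.na(rows[[1]]$structure_id))
})

test_that("rows order experimental structures before models", {
  mk <- function(id, source) {
    s <- placed_structure(data.frame(chain = "A", resno = 1, aa3 = "MET",
                                     x = 0, y = 0, z = 0),
                          chain_protein = c(A = "P1"),
                          structure_id = id, source = source)
    s
  }
  catalog <- read_isoform_catalog(write_lines(c(
    "gene_id\tprotein_id\tprincipal\tsequence", "G1\tP1\t1\tM")))
  ctx <- build_structure_context(list(mk("zz_model", "model"),
                                      mk("aa_exp", "experimental")),
                                 catalog)
  rows <- annotate_variant(list(protein_id = "P1", position = 1L,
                                ref_aa = "M", alt_aa = "V"),
                           load_annotation_tables(), ctx)
  expect_equal(vapply(rows, function(r) r$structure_id, ""),
               c("aa_exp", "zz_model"))
})

test_that("neighbor evidence never shrinks as the cutoff grows", {
  set.seed(7)
  fx <- generate_validation_set(fixture_spec(seed = 3), dir = tempfile())
  catalog <- read_isoform_catalog(fx$catalog)
  store <- load_annotation_tables(fx$features, fx$somatic, fx$predictions)
  idx <- read_structure_index(fx$structure_index)
  ctx <- build_structure_context(structvar:::load_structures(idx), catalog)
  sub <- list(protein_id = fx$spec$protein_a, position = 16L,
              ref_aa = substr(read_isoform_catalog(fx$catalog)$sequence[1],
                              16, 16),
              alt_aa = "X")
  sub$alt_aa <- structvar:::fixture_alt_aa(sub$ref_aa)
  ev_small <- annotate_variant(sub, store, ctx, cutoff = 4.6)[[1]]$evidence
  ev_big <- annotate_variant(sub, store, ctx, cutoff = 8)[[1]]$evidence
  small_nbr <- grep("^(neighbor_site|interface)", ev_small, value = TRUE)
  big_prefix <- sub("\\|.*$", "", grep("^(neighbor_site|interface)", ev_big,
                                       value = TRUE))
  for (e in sub("\\|.*$", "", small_nbr))
    expect_true(e %in% big_prefix)
})
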