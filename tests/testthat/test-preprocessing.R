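test_that("mask_sentence replaces every lexicon match with the sentinels", {
  prot <- tiny_proteins()
  phen <- tiny_phenotypes()
  sent <- paste0("BRCA1, BRCA2, PALB2 and RAD51C should be included in the ",
                 "genetic testing panel of breast cancer patients in ",
                 "Argentina.")
  masked <- mask_sentence(sent, prot, phen)
  expect_identical(masked,
                   paste0("PROT, BRCA2, PALB2 and RAD51C should be included ",
                          "in the genetic testing panel of PHENO patients ",
                          "in Argentina."))
  # idempotent
  expect_identical(mask_sentence(masked, prot, phen), masked)
  # no matches -> identity
  expect_identical(mask_sentence("nothing here", prot, phen),
                   "nothing here")

  # all entities are masked, not only a focal pair; sentinels sit inline
  # like "patients with PHENO (AML) ... the fusion gene PROT-ETO"
  prot2 <- lexicon(list(A = "AML1"), "protein")
  phen2 <- lexicon(list(B = "acute myeloid leukemia"), "phenotype")
  m2 <- mask_sentence(
    "Some patients with acute myeloid leukemia (AML) carry AML1-ETO.",
    prot2, phen2)
  expect_match(m2, "patients with PHENO \\(AML\\)")
  expect_match(m2, "PROT-ETO", fixed = TRUE)

  # record-level wrapper
  rec <- list(sentence = sent)
  expect_identical(mask_entities(rec, prot, phen), masked)
})

test_that("masking removes all lexicon surface forms (randomized)", {
  ds <- generate_dataset(synth_config(n_labeled = 200L, n_unlabeled = 0L,
                                      n_test = 0L, seed = 31L))
  all_names <- c(unlist(ds$proteins$entries), unlist(ds$phenotypes$entries))
  for (i in seq_len(200L)) {
    sent <- ds$labeled$sentence[[i]]
    masked <- mask_sentence(sent, ds$proteins, ds$phenotypes)
    hit <- vapply(all_names, function(nm)
      grepl(nm, masked, ignore.case = TRUE, fixed = FALSE), TRUE)
    expect_false(any(hit), info = sent)
    # sentinel count equals the oracle count of non-overlapping matches
    orc <- oracle_scan(sent, list(ds$proteins, ds$phenotypes))
    n_sentinel <- lengths(regmatches(masked,
                                     gregexpr("PROT|PHENO", masked)))
    expect_equal(n_sentinel, nrow(orc), info = sent)
  }
})

test_that("tokenize preserves sentinels, lowercases and splits on
           non-alphanumerics", {
  expect_equal(tokenize("PROT causes PHENO."), c("PROT", "causes", "PHENO"))
  expect_equal(tokenize("PROT-ETO fusion"), c("PROT", "eto", "fusion"))
  expect_equal(tokenize(""), character())
  expect_equal(tokenize("Wnt/beta-catenin (PHENO)!"),
               c("wnt", "beta", "catenin", "PHENO"))
  cfg <- preprocess_config(lowercase = FALSE)
  expect_equal(tokenize("Big PROT", cfg), c("Big", "PROT"))
})

test_that("build_vocab orders by frequency then lexicographically, honours
           min_token_freq, and is deterministic", {
  cfg <- preprocess_config()
  seqs <- list(c("PROT", "x", "PHENO"), c("x", "y"))
  v <- build_vocab(seqs, cfg)
  expect_equal(unname(v[c("<pad>", "<unk>", "PROT", "PHENO")]), 0:3)
  expect_lt(v[["x"]], v[["y"]])  # freq 2 before freq 1

  v2 <- build_vocab(seqs, preprocess_config(min_token_freq = 2L))
  expect_false("y" %in% names(v2))
  expect_true("x" %in% names(v2))

  expect_identical(build_vocab(seqs, cfg), v)
  # empty input -> reserved tokens only
  expect_length(build_vocab(list(), cfg), 4L)
  # ties broken lexicographically
  v3 <- build_vocab(list(c("b", "a")), cfg)
  expect_lt(v3[["a"]], v3[["b"]])
})

test_that("encode_pad pads, truncates and maps OOV to unk", {
  cfg <- preprocess_config(max_len = 5L)
  v <- build_vocab(list(c("a", "b", "c")), cfg)
  expect_equal(encode_pad(c("a", "b", "c"), v, cfg),
               c(v[["a"]], v[["b"]], v[["c"]], 0L, 0L))
  expect_length(encode_pad(letters[1:7], v, cfg), 5L)
  expect_equal(encode_pad(c("a", "zzz", "b"), v, cfg)[2L], 1L)  # unk

  # decode(encode(x)) recovers in-vocab tokens up to L
  toks <- c("a", "c", "b")
  ids <- encode_pad(toks, v, cfg)
  expect_equal(names(v)[ids[1:3] + 1L], toks)
})

test_that("stratified_split honours the per-class rounding rule", {
  ds <- generate_dataset(synth_config(n_labeled = 100L, n_unlabeled = 0L,
                                      n_test = 0L, label_noise = 0,
                                      seed = 17L))
  sp <- stratified_split(ds$labeled, split_config(seed = 4L))
  expect_equal(vapply(sp, nrow, 0L),
               c(train = 60L, validation = 20L, test = 20L))
  expect_equal(vapply(sp, function(x) sum(x$label), 0L),
               c(train = 30L, validation = 10L, test = 10L))
  # disjoint and exhaustive
  keys <- lapply(sp, comention_keys)
  expect_equal(sum(lengths(keys)), 100L)
  expect_equal(anyDuplicated(unlist(keys)), 0L)

  # 7 pos / 3 neg: per class round(0.2 n) = 1/1, remainder to train
  small <- ds$labeled[c(which(ds$labeled$label == 1L)[1:7],
                        which(ds$labeled$label == 0L)[1:3]), ]
  sp2 <- stratified_split(small, split_config(seed = 1L))
  expect_equal(vapply(sp2, nrow, 0L),
               c(train = 6L, validation = 2L, test = 2L))
  expect_equal(vapply(sp2, function(x) sum(x$label), 0L),
               c(train = 5L, validation = 1L, test = 1L))

  # deterministic given seed; different seed gives a different shuffle
  sp3 <- stratified_split(ds$labeled, split_config(seed = 4L))
  expect_identical(sp, sp3)

  # a class with < 3 members cannot populate all splits
  toosmall <- ds$labeled[c(which(ds$labeled$label == 1L)[1:2],
                           which(ds$labeled$label == 0L)[1:5]), ]
  expect_error(stratified_split(toosmall, split_config()), "need >= 3")
})

test_that("split class proportions stay within one record of global", {
  ds <- generate_dataset(synth_config(n_labeled = 137L, n_unlabeled = 0L,
                                      n_test = 0L, positive_fraction = 0.3,
                                      seed = 23L))
  sp <- stratified_split(ds$labeled, split_config(seed = 8L))
  glob <- mean(ds$labeled$label)
  for (part in sp) {
    expect_lte(abs(sum(part$label) - glob * nrow(part)), 1)
  }
})

test_that("encode_records builds a consistent encoded_set", {
  ds <- generate_dataset(synth_config(n_labeled = 25L, n_unlabeled = 0L,
                                      n_test = 0L, seed = 3L))
  pre <- small_pre_config()
  es <- encode_records(ds$labeled, ds$proteins, ds$phenotypes, cfg = pre)
  expect_s3_class(es, "encoded_set")
  expect_equal(dim(es$ids), c(25L, pre$max_len))
  expect_true(all(es$ids >= 0L & es$ids < length(es$vocab)))
  expect_equal(es$label, ds$labeled$label)
  # every sentence contains both sentinels after masking
  expect_true(all(apply(es$ids, 1L, function(r) all(c(2L, 3L) %in% r))))

  # subset and rbind bookkeeping
  a <- encoded_subset(es, 1:10)
  b <- encoded_subset(es, 11:25)
  ab <- encoded_rbind(a, b)
  expect_equal(ab$ids, es$ids)
  expect_equal(ab$key, es$key)
})
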