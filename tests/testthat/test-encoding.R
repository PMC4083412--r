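test_that("the default manifest has the documented layout", {
  man <- default_manifest()
  expect_equal(nrow(man), 184L)
  expect_equal(anyDuplicated(man$slot), 0L)
  counts <- table(man$group)
  expect_equal(unname(counts[c("ENV", "SEQ_ONEHOT", "LOCAL", "EVO",
                               "POTENTIAL", "NET_CENTRALITY",
                               "NET_COMPOSITION", "NET_SIZE")]),
               c(2L, 80L, 4L, 3L, 2L, 72L, 20L, 1L),
               ignore_attr = TRUE)
})

test_that("one-hot encoding puts exactly one 1 at the residue's index", {
  v <- one_hot("ALA")
  expect_equal(unname(v[1]), 1)
  expect_equal(sum(v), 1)
  for (aa in rinstab:::AA3) {
    vv <- one_hot(aa)
    expect_equal(sum(vv), 1)
    expect_equal(sum(vv == 1), 1L)
    expect_equal(names(which(vv == 1)), aa)
  }
  expect_equal(one_hot("W"), one_hot("TRP"))
  expect_error(one_hot("XYZ"), "non-standard")
})

test_that("variant subsets have the documented sizes and are sub-vectors", {
  man <- default_manifest()
  expect_equal(nrow(variant_subset(man, "full")), 184L)
  expect_equal(nrow(variant_subset(man, "no_topology")), 91L)
  expect_equal(nrow(variant_subset(man, "minimal")), 90L)
  expect_error(variant_subset(man, "bogus"))
  expect_true(all(variant_subset(man, "no_topology")$slot %in% man$slot))
  expect_true(all(variant_subset(man, "minimal")$slot %in% man$slot))
})

encode_ctx <- local({
  ctx <- NULL
  function() {
    if (is.null(ctx)) {
      s <- annotate_structure(make_fixture_structure("helix", 15))
      g <- build_rin(s)
      ev <- suppressWarnings(evo_profile(s, NULL))
      pt <- potential_scores(s, g)
      ctx <<- list(s = s, g = g, ev = ev, pt = pt)
    }
    ctx
  }
})

test_that("encoding a mutation yields a finite, named 184-vector", {
  cc <- encode_ctx()
  m <- list(position = "8", wt = "A", mut = "W", ph = 7, temp = 25)
  v <- encode_mutation(m, cc$s, cc$g, cc$ev, cc$pt)
  expect_length(v, 184L)
  expect_true(all(is.finite(v)))
  expect_equal(names(v), default_manifest()$slot)
  expect_equal(unname(v["ph"]), 7)
  expect_equal(unname(v["mut_TRP"]), 1)
  expect_equal(unname(v["network_size"]), 15)
  # deterministic
  expect_identical(v, encode_mutation(m, cc$s, cc$g, cc$ev, cc$pt))
})

test_that("terminal sites zero out the missing neighbour blocks", {
  cc <- encode_ctx()
  m1 <- list(position = "1", wt = "A", mut = "G", ph = 7, temp = 25)
  v1 <- encode_mutation(m1, cc$s, cc$g, cc$ev, cc$pt)
  left <- v1[paste0("left_", rinstab:::AA3)]
  expect_equal(sum(left), 0)
  expect_equal(sum(v1[paste0("right_", rinstab:::AA3)]), 1)
  expect_true(all(v1[grep("^net_left_", names(v1))] == 0))
})

test_that("changing only the mutant residue changes only its one-hot block", {
  cc <- encode_ctx()
  base <- list(position = "8", wt = "A", mut = "W", ph = 7, temp = 25)
  alt <- modifyList(base, list(mut = "K"))
  v1 <- encode_mutation(base, cc$s, cc$g, cc$ev, cc$pt)
  v2 <- encode_mutation(alt, cc$s, cc$g, cc$ev, cc$pt)
  diff <- names(v1)[v1 != v2]
  expect_setequal(diff, c("mut_TRP", "mut_LYS"))
})

test_that("wild-type mismatches and unknown sites are rejected", {
  cc <- encode_ctx()
  expect_error(encode_mutation(list(position = "8", wt = "G", mut = "W",
                                    ph = 7, temp = 25),
                               cc$s, cc$g, cc$ev, cc$pt),
               "wild-type check failed")
  expect_error(encode_mutation(list(position = "99", wt = "A", mut = "W",
                                    ph = 7, temp = 25),
                               cc$s, cc$g, cc$ev, cc$pt),
               "site not found")
})

test_that("variant vectors are exact sub-vectors of the full vector", {
  cc <- encode_ctx()
  m <- list(position = "8", wt = "A", mut = "W", ph = 7, temp = 25)
  full <- encode_mutation(m, cc$s, cc$g, cc$ev, cc$pt)
  for (variant in c("no_topology", "minimal")) {
    man <- variant_subset(default_manifest(), variant)
    v <- encode_mutation(m, cc$s, cc$g, cc$ev, cc$pt, manifest = man)
    expect_identical(unname(v), unname(full[man$slot]))
  }
})

test_that("permuting the manifest permutes the vector identically", {
  cc <- encode_ctx()
  m <- list(position = "8", wt = "A", mut = "W", ph = 7, temp = 25)
  man <- default_manifest()
  set.seed(1)
  perm <- man[sample(nrow(man)), ]
  v <- encode_mutation(m, cc$s, cc$g, cc$ev, cc$pt)
  vp <- encode_mutation(m, cc$s, cc$g, cc$ev, cc$pt, manifest = perm)
  expect_identical(unname(vp), unname(v[perm$slot]))
})

test_that("encode_table builds a matrix over several structures", {
  structs <- fixture_pair()
  mt <- simulate_mutation_table(structs, 25, seed = 13)
  X <- encode_table(mt, structs)
  expect_equal(dim(X), c(25L, 184L))
  expect_true(all(is.finite(X)))
  expect_equal(colnames(X), default_manifest()$slot)
})

test_that("manifest round trips through TSV and hashes stably", {
  man <- default_manifest()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(man, tf)
  back <- read.delim(tf, stringsAsFactors = FALSE)
  expect_equal(back$slot, man$slot)
  expect_equal(manifest_hash(man), manifest_hash(default_manifest()))
  expect_false(manifest_hash(man) ==
               manifest_hash(variant_subset(man, "minimal")))
})
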