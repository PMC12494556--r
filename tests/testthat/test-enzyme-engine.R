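comp_of <- function(x) comp_label(composition_of(x))

test_that("glucosidase rules trim the cap in the canonical order", {
  expect_identical(comp_of(apply_gcs1("Glc3Man9GlcNAc2")$product), "Hex11HexNAc2")
  expect_error(apply_gcs1("Man9GlcNAc2"), class = "glyco_not_substrate")
  # remaining glucose of the monoglucosylated form is alpha-1,3, not GCSI's
  expect_error(apply_gcs1("Glc1Man9GlcNAc2"), class = "glyco_not_substrate")
  expect_identical(comp_of(apply_gcs2("Glc2Man9GlcNAc2")$product), "Hex10HexNAc2")
  expect_identical(structure_name(apply_gcs2("Glc1Man9GlcNAc2")$product),
                   "Man9GlcNAc2")
  expect_error(apply_gcs2("Glc3Man9GlcNAc2"), class = "glyco_not_substrate")
})

test_that("UGGT reglucosylates only glucose-free glycans with an intact A-tip", {
  re <- apply_uggt("Man9GlcNAc2")
  expect_identical(structure_name(re$product), "Glc1Man9GlcNAc2")
  expect_length(re$released, 0)
  expect_error(apply_uggt("Glc1Man9GlcNAc2"), class = "glyco_not_substrate")
  # after endomannosidase the acceptor mannose is gone for good
  post_endom <- apply_endom("Glc1Man9GlcNAc2")$product
  expect_error(apply_uggt(post_endom), class = "glyco_not_substrate")
})

test_that("MNS4/MNS5 trims the C-branch tip and exposes the OS9 signal", {
  single <- apply_mns45("Glc1Man9GlcNAc2")
  expect_identical(comp_of(single$product), "Hex9HexNAc2")
  expect_true(os9_signal_exposed(single$product))
  expect_false(os9_signal_exposed("Glc1Man9GlcNAc2"))
  extended <- apply_mns45("Glc1Man9GlcNAc2", extended = TRUE)
  expect_identical(comp_of(extended$product), "Hex8HexNAc2")
  expect_identical(structure_name(extended$product), "Glc1Man7GlcNAc2")
  expect_error(apply_mns45("Glc1Man7GlcNAc2"), class = "glyco_not_substrate")
})

test_that("endomannosidase removes the Glc-Man disaccharide exactly once", {
  r <- apply_endom("Glc1Man9GlcNAc2")
  expect_identical(comp_of(r$product), "Hex8HexNAc2")
  expect_identical(structure_name(r$product), "Man8GlcNAc2-A")
  expect_identical(comp_label(r$released[[1]]), "Hex2")
  r7 <- apply_endom("Glc1Man7GlcNAc2")
  expect_identical(comp_of(r7$product), "Hex6HexNAc2")
  expect_error(apply_endom("Man9GlcNAc2"), class = "glyco_not_substrate")
  expect_error(apply_endom("Glc2Man9GlcNAc2"), class = "glyco_not_substrate")
  expect_error(apply_endom("Glc3Man9GlcNAc2"), class = "glyco_not_substrate")
})

test_that("jack bean mannosidase respects glucose caps and the beta core", {
  expect_identical(comp_of(apply_jbm("Man9GlcNAc2")$product), "Hex1HexNAc2")
  expect_identical(comp_of(apply_jbm("Glc1Man7GlcNAc2")$product), "Hex5HexNAc2")
  expect_identical(comp_of(apply_jbm("Glc1Man9GlcNAc2")$product), "Hex5HexNAc2")
  core <- parse_structure("Man(b1-4)GlcNAc(b1-4)GlcNAc")
  expect_identical(comp_of(apply_jbm(core)$product), "Hex1HexNAc2")
  # partial iterations walk the deterministic Hex ladder
  its <- vapply(0:4, function(k) {
    comp_of(apply_jbm("Glc1Man9GlcNAc2", iterations = k)$product)
  }, character(1))
  expect_identical(its, c("Hex10HexNAc2", "Hex8HexNAc2", "Hex6HexNAc2",
                          "Hex5HexNAc2", "Hex5HexNAc2"))
})

test_that("every rule conserves residues on every registry structure", {
  rules <- list(gcs1 = apply_gcs1, gcs2 = apply_gcs2, uggt = apply_uggt,
                mns45 = apply_mns45,
                mns45x = function(t) apply_mns45(t, extended = TRUE),
                endom = apply_endom, jbm = apply_jbm)
  for (nm in glycan_registry()) {
    tree <- glycan_canonical(nm)
    input <- composition_of(tree)
    for (rn in names(rules)) {
      res <- tryCatch(rules[[rn]](tree), glyco_not_substrate = function(e) NULL)
      if (is.null(res)) next
      balance <- Reduce(`+`, res$released, composition_of(res$product))
      if (rn == "uggt") {
        expect_true(balance == input + glycan_comp(hex = 1),
                    info = paste(nm, rn))
      } else {
        expect_true(balance == input, info = paste(nm, rn))
      }
    }
  }
})

test_that("the limit JBM digest is an idempotent fixpoint", {
  for (nm in glycan_registry()) {
    once <- apply_jbm(glycan_canonical(nm))$product
    twice <- apply_jbm(once)$product
    expect_identical(format_structure(twice), format_structure(once), info = nm)
    expect_length(apply_jbm(once)$released, 0)
  }
})

test_that("no rule sequence without UGGT ever increases the hexose count", {
  rules <- c("gcs1", "gcs2", "a12man", "mns45_c", "mns45_b", "endom")
  set.seed(99)
  for (rep in 1:30) {
    tree <- glycan_canonical(sample(glycan_registry(), 1))
    hex <- composition_of(tree)[["hex"]]
    for (step in 1:6) {
      opts <- unlist(lapply(sample(rules), function(r) {
        glycotrim:::.rule_steps(tree, r)
      }), recursive = FALSE)
      if (length(opts) == 0) break
      tree <- opts[[sample.int(length(opts), 1)]]$product
      h2 <- composition_of(tree)[["hex"]]
      expect_lte(h2, hex)
      hex <- h2
    }
  }
})

test_that("a glucose cap protects the A-arm from JBM on every glucosylated start", {
  glucosylated <- c("Glc3Man9GlcNAc2", "Glc2Man9GlcNAc2", "Glc1Man9GlcNAc2",
                    "Glc1Man8GlcNAc2", "Glc1Man7GlcNAc2")
  a_arm <- c(glycotrim:::.pos$a_stem, glycotrim:::.pos$a_tip)
  for (nm in glucosylated) {
    start <- glycan_canonical(nm)
    prod <- apply_jbm(start)$product
    expect_equal(sum(prod$sugar == "Glc"), sum(start$sugar == "Glc"), info = nm)
    expect_true(all(a_arm %in% prod$residue_id), info = nm)
  }
})

test_that("reachable closure matches brute-force recursion and known chains", {
  # deglucosylation is a linear chain
  chain <- reachable_structures("Glc3Man9GlcNAc2", rules = c("gcs1", "gcs2"))
  expect_identical(sort(chain$name),
                   sort(c("Glc3Man9GlcNAc2", "Glc2Man9GlcNAc2",
                          "Glc1Man9GlcNAc2", "Man9GlcNAc2")))
  # one mannosidase step on Man9 gives exactly the three Man8 isomers
  one <- reachable_structures("Man9GlcNAc2", rules = "a12man", max_steps = 1)
  expect_setequal(one$name[one$n_steps == 1],
                  c("Man8GlcNAc2-A", "Man8GlcNAc2-B", "Man8GlcNAc2-C"))
  # zero steps returns the start alone
  zero <- reachable_structures("Glc1Man7GlcNAc2", max_steps = 0)
  expect_equal(nrow(zero), 1L)
  expect_identical(zero$name, "Glc1Man7GlcNAc2")
  # BFS equals DFS enumeration on all registry starts up to depth 4
  rules <- c("gcs1", "gcs2", "uggt", "a12man", "mns45_c", "mns45_b")
  for (nm in glycan_registry()) {
    bfs <- sort(reachable_structures(nm, rules = rules, max_steps = 4)$structure)
    expect_identical(bfs, oracle_reachable(nm, rules, 4), info = nm)
  }
})

test_that("the OS9 signal state is consistent across all reachable structures", {
  all_states <- reachable_structures("Glc3Man9GlcNAc2")
  for (i in seq_len(nrow(all_states))) {
    tree <- all_states$tree[[i]]
    c_stem <- glycotrim:::.pos$c_stem
    manual <- c_stem %in% tree$residue_id &&
      !any(!is.na(tree$parent) & tree$parent == c_stem)
    expect_identical(os9_signal_exposed(tree), manual, info = all_states$name[i])
  }
})

test_that("isomer inference resolves isobaric compositions from digestion evidence", {
  # glucose-capped candidate: limit JBM stops at Hex5
  glc <- infer_isomer("Hex8HexNAc2", jbm_limit = "Hex5HexNAc2")
  expect_identical(glc$name, "Glc1Man7GlcNAc2")
  # trimming to Hex1 excludes every glucosylated candidate
  free <- infer_isomer("Hex8HexNAc2", jbm_limit = "Hex1HexNAc2")
  expect_true(nrow(free) >= 3)
  expect_true(all(free$n_glc == 0))
  expect_true(all(c("Man8GlcNAc2-A", "Man8GlcNAc2-B", "Man8GlcNAc2-C") %in% free$name))
  # without evidence Hex9 stays ambiguous between Man9 and Glc1Man8
  amb <- infer_isomer("Hex9HexNAc2")
  expect_true(all(c("Man9GlcNAc2", "Glc1Man8GlcNAc2") %in% amb$name))
  # glucosylated candidates come first, and order is deterministic
  expect_true(all(diff(amb$n_glc) <= 0))
  expect_identical(amb, infer_isomer("Hex9HexNAc2"))
  # contradictory evidence yields an empty candidate list with a diagnostic
  expect_warning(none <- infer_isomer("Hex8HexNAc2", jbm_limit = "Hex3HexNAc2"),
                 "no candidate")
  expect_equal(nrow(none), 0L)
})

test_that("inference rejects non-N-glycan compositions", {
  expect_error(infer_isomer("HexNAc1"), class = "glyco_validation_error")
})
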