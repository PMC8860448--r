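# bounds used throughout: lower = 1, upper = 3
test_bounds <- list(lower = 1, upper = 3)

# expression value per symbolic state; "missing" genes are absent from expr
expr_value <- c(below = 0.5, above = 2, high = 4)

spec_row <- function(gene, state) {
  switch(state,
         specific = data.frame(gene = gene, log2fc = 2, q = 0.01),
         neutral = data.frame(gene = gene, log2fc = 0, q = 0.5),
         verylow = data.frame(gene = gene, log2fc = -2, q = 0.01))
}

test_that("VM cascade equals the boolean formula over every input combination", {
  grid <- expand.grid(q_vm = c(0.01, 0.5), lfc_vm = c(1.5, -1.5),
                      q_mfb = c(0.01, 0.5), q_str = c(0.01, 0.5),
                      expr_state = c("missing", "below", "above"),
                      flag = c("none", "verylow"),
                      stringsAsFactors = FALSE)
  ids <- sprintf("P%03d", seq_len(nrow(grid)))
  de_vm <- fake_de(ids, grid$q_vm, grid$lfc_vm)
  de_mfb <- fake_de(ids, grid$q_mfb, ifelse(grid$q_mfb < 0.05, 1.2, 0))
  de_str <- fake_de(ids, grid$q_str, ifelse(grid$q_str < 0.05, 1.2, 0))
  keep <- grid$expr_state != "missing"
  expr <- setNames(expr_value[grid$expr_state[keep]], ids[keep])
  spec <- do.call(rbind, lapply(which(grid$flag == "verylow"),
                                function(i) spec_row(ids[i], "verylow")))

  trail <- filter_vm(de_vm, de_mfb, de_str, expr, spec, test_bounds)
  for (i in seq_len(nrow(grid))) {
    r1 <- grid$q_vm[i] < 0.05 && grid$lfc_vm[i] > 0
    r2a <- grid$expr_state[i] == "above"
    r2b <- r1 && grid$q_mfb[i] < 0.05 && grid$q_str[i] < 0.05
    r3 <- grid$flag[i] == "verylow"
    expect_identical(trail$pass_vm[i], vm_pass_formula(r1, r2a, r2b, r3),
                     label = paste("combo", i))
    expect_identical(trail$vm_rule1[i], r1)
    expect_identical(trail$vm_rule2a[i], r2a)
    expect_identical(trail$vm_rule2b[i], r2b)
    expect_identical(trail$vm_rule3_removed[i], r3)
  }
})

test_that("VM cascade honours its documented edge rules", {
  ids <- c("hit", "insig", "rescue")
  # hit: enriched + expressed; insig: q too large; rescue: expressed-below
  # but enriched in all three regions
  de_vm <- fake_de(ids, c(0.01, 0.2, 0.01), c(2, 2, 2))
  de_mfb <- fake_de(ids, c(0.5, 0.01, 0.01), c(0, 2, 2))
  de_str <- fake_de(ids, c(0.5, 0.01, 0.01), c(0, 2, 2))
  expr <- c(hit = 2, insig = 2, rescue = 0.2)
  trail <- filter_vm(de_vm, de_mfb, de_str, expr, NULL, test_bounds)
  expect_equal(trail$pass_vm, c(TRUE, FALSE, TRUE))
})

test_that("striatum cascade equals the boolean formula over every input combination", {
  grid <- expand.grid(q_str = c(0.01, 0.5), lfc_str = c(1.5, -1.5),
                      q_vm = c(0.01, 0.5), q_mfb = c(0.01, 0.5),
                      lfc_vm = c(1.5, 0.5), lfc_mfb = c(1.5, 0.5),
                      expr_state = c("missing", "below", "above", "high"),
                      spec_mid = c("specific", "neutral", "verylow"),
                      spec_str = c("specific", "neutral", "verylow"),
                      stringsAsFactors = FALSE)
  ids <- sprintf("P%04d", seq_len(nrow(grid)))
  de_vm <- fake_de(ids, grid$q_vm, grid$lfc_vm)
  de_mfb <- fake_de(ids, grid$q_mfb, grid$lfc_mfb)
  de_str <- fake_de(ids, grid$q_str, grid$lfc_str)
  keep <- grid$expr_state != "missing"
  ev <- c(expr_value, high = 4)
  expr <- setNames(ev[grid$expr_state[keep]], ids[keep])
  spec_mid <- do.call(rbind, lapply(seq_along(ids), function(i)
    spec_row(ids[i], grid$spec_mid[i])))
  spec_str <- do.call(rbind, lapply(seq_along(ids), function(i)
    spec_row(ids[i], grid$spec_str[i])))

  trail <- filter_str(de_vm, de_mfb, de_str, expr, spec_mid, spec_str,
                      test_bounds)
  enr <- function(q, lfc) q < 0.05 & lfc > 0
  r1 <- enr(grid$q_str, grid$lfc_str)
  r2a <- enr(grid$q_vm, grid$lfc_vm) | enr(grid$q_mfb, grid$lfc_mfb)
  r2b <- grid$lfc_vm > 1 & grid$lfc_mfb > 1
  specific <- grid$spec_mid == "specific" | grid$spec_str == "specific"
  r2c <- grid$expr_state == "high" & specific
  r3a <- grid$expr_state %in% c("above", "high")
  r3b <- enr(grid$q_vm, grid$lfc_vm) & enr(grid$q_mfb, grid$lfc_mfb) & r1
  r4 <- grid$spec_mid == "verylow" | grid$spec_str == "verylow"
  expected <- mapply(str_pass_formula, r1, r2a, r2b, r2c, r3a, r3b, r4)
  expect_identical(trail$pass_str, unname(expected))
  expect_identical(trail$str_rule1, unname(r1))
  expect_identical(trail$str_rule2a, unname(r2a))
  expect_identical(trail$str_rule2b, unname(r2b))
  expect_identical(trail$str_rule2c, unname(r2c))
  expect_identical(trail$str_rule3a, unname(r3a))
  expect_identical(trail$str_rule3b, unname(r3b))
  expect_identical(trail$str_rule4_removed, unname(r4))
})

test_that("striatum rescue by large VM and MFB fold changes works without significance", {
  ids <- "P1"
  de_vm <- fake_de(ids, 0.3, 1.5)
  de_mfb <- fake_de(ids, 0.4, 1.5)
  de_str <- fake_de(ids, 0.01, 2)
  expr <- c(P1 = 2)
  trail <- filter_str(de_vm, de_mfb, de_str, expr, NULL, NULL, test_bounds)
  expect_true(trail$pass_str)
  expect_true(trail$str_rule2b)
  expect_false(trail$str_rule2a)
})

test_that("relaxing the enrichment FDR threshold never shrinks pass sets", {
  set.seed(8)
  n <- 200
  ids <- sprintf("P%03d", 1:n)
  de_vm <- fake_de(ids, runif(n), rnorm(n))
  de_mfb <- fake_de(ids, runif(n), rnorm(n))
  de_str <- fake_de(ids, runif(n), rnorm(n))
  expr <- setNames(runif(n, 0, 4), ids)
  t1 <- filter_vm(de_vm, de_mfb, de_str, expr, NULL, test_bounds,
                  filter_config(q_enrich = 0.05))
  t2 <- filter_vm(de_vm, de_mfb, de_str, expr, NULL, test_bounds,
                  filter_config(q_enrich = 0.2))
  expect_true(all(t1$pass_vm <= t2$pass_vm))
  s1 <- filter_str(de_vm, de_mfb, de_str, expr, NULL, NULL, test_bounds,
                   filter_config(q_enrich = 0.05))
  s2 <- filter_str(de_vm, de_mfb, de_str, expr, NULL, NULL, test_bounds,
                   filter_config(q_enrich = 0.2))
  expect_true(all(s1$pass_str <= s2$pass_str))
})

random_trails <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("P%03d", seq_len(n))
  vm <- data.frame(protein_id = ids, pass_vm = runif(n) < 0.4)
  st <- data.frame(protein_id = sample(ids), pass_str = runif(n) < 0.4)
  list(vm = vm, st = st, ids = ids)
}

test_that("union partition matches brute-force set algebra", {
  empty <- random_trails(0, 1)
  p0 <- combine_union(empty$vm, empty$st)
  expect_equal(unname(p0$counts), rep(0L, 4))

  for (seed in 1:5) {
    tr <- random_trails(120, seed)
    p <- combine_union(tr$vm, tr$st)
    vm_set <- tr$vm$protein_id[tr$vm$pass_vm]
    st_set <- tr$st$protein_id[tr$st$pass_str]
    expect_setequal(p$vm_only, setdiff(vm_set, st_set))
    expect_setequal(p$str_only, setdiff(st_set, vm_set))
    expect_setequal(p$both, intersect(vm_set, st_set))
    expect_equal(p$counts[["vm_only"]] + p$counts[["str_only"]] +
                   p$counts[["both"]], p$counts[["union"]])
    expect_length(intersect(p$vm_only, p$both), 0)
  }
})

test_that("ontology-input sizes decompose additively into only + enriched", {
  set.seed(12)
  tr <- random_trails(150, 3)
  p <- combine_union(tr$vm, tr$st)
  de <- fake_de(tr$ids, runif(150), rnorm(150))
  rs <- region_enriched_sets(p, de, q_max = 0.3)
  expect_equal(rs$counts[["vm_go_input"]],
               length(p$vm_only) + rs$counts[["vm_enriched"]])
  expect_equal(rs$counts[["str_go_input"]],
               length(p$str_only) + rs$counts[["str_enriched"]])

  # no differential hits: inputs reduce to the region-only sets
  de_null <- fake_de(tr$ids, rep(1, 150), rnorm(150))
  rs0 <- region_enriched_sets(p, de_null)
  expect_setequal(rs0$vm_go_input, p$vm_only)
  expect_setequal(rs0$str_go_input, p$str_only)
})

test_that("planted compartment bias is recovered in the shared set", {
  sim <- gen_proteomics(proteomics_sim_config(seed = 5))
  tr <- sim$truth
  both <- tr$protein_id[tr$enriched_in == "VM,MFB,STR"]
  partition <- list(vm_only = character(0), str_only = character(0),
                    both = both, union = both)
  la <- subset_proteins(normalize_log2(sim$matrix), both)
  de <- differential(la,
                     samples_where(sim$annotations, "VM", "APEX2"),
                     samples_where(sim$annotations, "STR", "APEX2"))
  rs <- region_enriched_sets(partition, de)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  expect_gte(jac(rs$vm_enriched, tr$protein_id[tr$bias == "VM"]), 0.8)
  expect_gte(jac(rs$str_enriched, tr$protein_id[tr$bias == "STR"]), 0.8)
})
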