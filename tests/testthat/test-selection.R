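# hand-built evidence tables around a single constructed instance
make_evidence <- function() {
  ann <- data.frame(
    metabolite_id = sprintf("m%02d", 1:10),
    subpathway = rep(c("sub_big", "sub_small"), c(6, 4)),
    superpathway = "Lipid")
  univ <- data.frame(
    metabolite_id = ann$metabolite_id,
    fold_change = c(3, 3, 3, 1.2, 3, 3, 3, 3, 1.1, 0.3),
    p_value = c(0.01, 0.01, 0.2, 0.01, 0.01, 0.01, 0.01, 0.01, 0.5, 0.01),
    q_value = 0.04, degenerate = FALSE)
  univ$log2_fc <- log2(univ$fold_change)
  univ$direction <- ifelse(univ$fold_change > 1, "up", "down")
  attr(univ, "contrast") <- "11Gy_TP1_vs_TP2"
  vip <- stats::setNames(c(1.5, 0.9, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5),
                         univ$metabolite_id)
  enrich <- data.frame(subpathway = "sub_big", superpathway = "Lipid",
                       N = 10, K = 6, n = 5, k = 5,
                       p_over = 0.01, p_under = 0.999)
  attr(enrich, "small_subpathways") <-
    data.frame(subpathway = "sub_small", K = 4)
  list(ann = ann, univ = univ, vip = vip, enrich = enrich)
}

test_that("composite rule is the intersection of its criteria", {
  ev <- make_evidence()
  sel <- composite_select(ev$univ, ev$vip, TRUE, ev$enrich, ev$ann)
  got <- sel$selected_metabolites$metabolite_id
  # m01 passes everything; m02 fails VIP; m03 fails p; m04 fails fc;
  # m05/m06 pass (sub_big); m07..m10 sit in the too-small subpathway
  expect_setequal(got, c("m01", "m05", "m06"))
  tab <- sel$table
  expect_match(tab$reasons[tab$metabolite_id == "m02"], "VIP")
  expect_match(tab$reasons[tab$metabolite_id == "m03"], "p-value")
  expect_match(tab$reasons[tab$metabolite_id == "m04"], "fold change")
  expect_match(tab$reasons[tab$metabolite_id == "m07"], "min size")
  expect_equal(sel$selected_subpathways, "sub_big")
  # selected set is a subset of every single-criterion pass set
  expect_true(all(abs(tab$log2_fc[tab$selected]) > 1))
  expect_true(all(tab$p_value[tab$selected] < 0.05))
  expect_true(all(tab$vip[tab$selected] > 1))
  # down-regulation passes the two-sided rule when the rest holds
  ev2 <- make_evidence()
  ev2$univ$fold_change[10] <- 0.3
  sel2 <- composite_select(ev2$univ, ev2$vip, TRUE, ev2$enrich, ev2$ann)
  expect_match(sel2$table$reasons[10], "min size")
})

test_that("unvalidated model blocks selection when required", {
  ev <- make_evidence()
  sel <- composite_select(ev$univ, ev$vip, FALSE, ev$enrich, ev$ann)
  expect_equal(nrow(sel$selected_metabolites), 0)
  expect_match(sel$table$reasons[1], "not validated")
  relaxed <- selection_thresholds(require_validated_model = FALSE)
  sel2 <- composite_select(ev$univ, ev$vip, FALSE, ev$enrich, ev$ann, relaxed)
  expect_gt(nrow(sel2$selected_metabolites), 0)
  # coverage mismatch is an error
  expect_error(composite_select(ev$univ, ev$vip[-1], TRUE, ev$enrich, ev$ann),
               "cover")
})

test_that("confounder filter subtracts sham markers and is idempotent", {
  ev <- make_evidence()
  cand <- composite_select(ev$univ, ev$vip, TRUE, ev$enrich, ev$ann)
  sham <- cand
  sham$contrast <- "0Gy_TP1_vs_TP2"
  sham$selected_metabolites <-
    data.frame(metabolite_id = c("m01", "m99"), direction = "up")
  sham$selected_subpathways <- character(0)
  out <- confounder_filter(cand, sham)
  expect_setequal(out$selected_metabolites$metabolite_id, c("m05", "m06"))
  expect_equal(out$table$reasons[out$table$metabolite_id == "m01"],
               "sham time drift")
  expect_equal(out$confounders_removed$metabolites, "m01")
  # idempotent
  again <- confounder_filter(out, sham)
  expect_equal(again$selected_metabolites, out$selected_metabolites)
  # empty sham set leaves the candidate unchanged
  sham0 <- sham
  sham0$selected_metabolites <- sham$selected_metabolites[0, ]
  expect_equal(confounder_filter(cand, sham0)$selected_metabolites,
               cand$selected_metabolites)
  # mismatched timepoint contrast is an error
  sham_bad <- sham
  sham_bad$contrast <- "0Gy_TP1_vs_TP3"
  expect_error(confounder_filter(cand, sham_bad), "mismatch")
})

test_that("venn partitions enumerate exclusive regions exactly", {
  out <- venn_partition(list(A = c("a", "b"), B = c("b", "c"), C = "b"))
  lookup <- stats::setNames(out$count, out$region)
  expect_equal(unname(lookup["A"]), 1)          # a
  expect_equal(unname(lookup["B"]), 1)          # c
  expect_equal(unname(lookup["A&B&C"]), 1)      # b
  expect_equal(unname(lookup["A&B"]), 0)
  expect_equal(sum(out$count), 3)               # conserves the union
  # identical sets: all mass in the full intersection
  out2 <- venn_partition(list(X = letters[1:3], Y = letters[1:3]))
  expect_equal(out2$count[out2$region == "X&Y"], 3)
  expect_equal(sum(out2$count), 3)
  # disjoint sets: all mass exclusive
  out3 <- venn_partition(list(X = "a", Y = "b"))
  expect_equal(sum(out3$count[out3$region %in% c("X", "Y")]), 2)
  expect_error(venn_partition(list(A = "a")), "2-4")
  expect_error(venn_partition(list("a", "b")), "named")
})

test_that("dose-response profile orders with a planted monotone effect", {
  ids <- sprintf("s%02d", 1:12)
  meta <- tiny_meta(ids, dose = rep(c(0, 8, 14), each = 4), timepoint = "TP2")
  set.seed(17)
  logv <- matrix(rnorm(12 * 3, 4, 0.05), 12, 3,
                 dimnames = list(ids, c("flat", "mono", "other")))
  logv[, "mono"] <- logv[, "mono"] + rep(c(0, 1, 2), each = 4)
  pp <- preprocess(abundance_matrix(exp(logv)), meta)
  prof <- dose_response_profile(pp$matrix, meta, c("flat", "mono"), "TP2")
  mono <- prof[prof$metabolite_id == "mono", ]
  expect_true(all(diff(mono$mean_log) > 0))
  flat <- prof[prof$metabolite_id == "flat", ]
  expect_lt(max(flat$mean_log) - min(flat$mean_log), 0.3)
  expect_equal(nrow(dose_response_profile(pp$matrix, meta, "flat", "TP2")), 3)
  expect_error(dose_response_profile(pp$matrix, meta, "nope", "TP2"),
               "unknown")
})
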