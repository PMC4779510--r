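# Geometry builders: element counts, insulation wiring, error handling.

LAB <- grid_labels()

# coupled edges between two label sets, honouring the masks
count_edges_between <- function(g, from, to) {
  lab <- g$labels; nr <- nrow(lab); nc <- ncol(lab)
  a_h <- lab[, -nc, drop = FALSE]; b_h <- lab[, -1L, drop = FALSE]
  a_v <- lab[-nr, , drop = FALSE]; b_v <- lab[-1L, , drop = FALSE]
  sum(g$h_couple & (((a_h %in% from) & (b_h %in% to)) |
                    ((b_h %in% from) & (a_h %in% to)))) +
  sum(g$v_couple & (((a_v %in% from) & (b_v %in% to)) |
                    ((b_v %in% from) & (a_v %in% to))))
}

test_that("chains have the requested composition and full coupling", {
  g <- build_chain(6, 1)
  expect_identical(dim(g$labels), c(1L, 7L))
  expect_identical(sum(g$labels == LAB[["AC"]]), 6L)
  expect_identical(sum(g$labels == LAB[["VM_ENDO"]]), 1L)
  expect_true(all(g$h_couple))
  g2 <- build_chain(1, 1)
  expect_identical(dim(g2$labels), c(1L, 2L))
  expect_identical(sum(g2$h_couple), 1L)
  expect_error(build_chain(0, 1))
  expect_error(build_chain(3, 0))
})

test_that("the insulated pacemaker layout has the published element counts", {
  g <- build_fig2_layout(vm_rows = 40, vm_cols = 30)
  expect_identical(sum(g$labels == LAB[["AC"]]), 150L)
  pk <- sum(g$labels %in% c(LAB[["PURKINJE"]], LAB[["PURKINJE_EXIT"]]))
  expect_identical(pk, 250L)
  expect_identical(sum(g$labels == LAB[["PURKINJE_EXIT"]]), 25L)
  expect_equal(g$layout$purkinje_length_mm, 16.5)
  # no direct AC/Purkinje-to-VM coupling outside the exit window
  vm <- c(LAB[["VM_ENDO"]], LAB[["VM_MID"]], LAB[["VM_EPI"]])
  expect_identical(count_edges_between(g, c(LAB[["AC"]], LAB[["PURKINJE"]]), vm), 0L)
  # the exit window does couple to the myocardium
  expect_gt(count_edges_between(g, LAB[["PURKINJE_EXIT"]], vm), 0L)
  expect_error(build_fig2_layout(vm_rows = 3, vm_cols = 10), "too small")
})

test_that("the idealized sheet has 40,000 myocytes and a 1000-cell pacemaker", {
  g <- build_fig9_layout()
  vm <- c(LAB[["VM_ENDO"]], LAB[["VM_MID"]], LAB[["VM_EPI"]])
  expect_identical(sum(g$labels %in% vm), 40000L)
  expect_identical(sum(g$labels == LAB[["AC"]]), 1000L)
  # 7.5 mm strand at dh = 0.33 mm: round(7.5/0.33) = 23 elements long
  pk <- matrix(g$labels %in% c(LAB[["PURKINJE"]], LAB[["PURKINJE_EXIT"]]),
               nrow(g$labels))
  pk_cols <- which(apply(pk, 2, any))
  expect_identical(length(pk_cols), 23L)
  expect_identical(count_edges_between(g, c(LAB[["AC"]], LAB[["PURKINJE"]]), vm), 0L)
})

test_that("the direct block is fully coupled and counts its ACs", {
  g <- build_direct_block(100, 30, 30)
  expect_false(isTRUE(g$layout$insulated))
  expect_identical(sum(g$labels == LAB[["AC"]]), 100L)
  vm <- c(LAB[["VM_ENDO"]], LAB[["VM_MID"]], LAB[["VM_EPI"]])
  # a 10x10 block touching VMs on all four sides: 40 coupled AC-VM edges
  expect_identical(count_edges_between(g, LAB[["AC"]], vm), 40L)
  expect_error(build_direct_block(100, 5, 5), "too small")
})

test_that("builders produce grids that satisfy every invariant", {
  for (g in list(build_chain(3, 2), build_fig2_layout(vm_rows = 8, vm_cols = 6),
                 build_fig9_layout(vm_rows = 10, vm_cols = 20),
                 build_direct_block(12, 10, 10)))
    expect_silent(validate_tissue_grid(g))
})
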