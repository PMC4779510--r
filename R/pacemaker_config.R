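# Procedural builders for the pacemaker geometries: 1D AC-VM chains, the
# insulated pacemaker + Purkinje exit layout, the idealized sheet, and a
# directly coupled (non-insulated) AC block.

.vm_label <- function(vm_type = c("ENDO", "MID", "EPI")) {
  vm_type <- match.arg(vm_type)
  switch(vm_type, ENDO = .LAB[["VM_ENDO"]], MID = .LAB[["VM_MID"]],
         EPI = .LAB[["VM_EPI"]])
}

# full coupling among non-VOID pixels minus every AC/PURKINJE <-> VM edge;
# PURKINJE_EXIT <-> VM edges stay coupled (the exit window)
.insulated_coupling <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  nv <- lab != .LAB[["VOID"]]
  h <- nv[, -nc, drop = FALSE] & nv[, -1L, drop = FALSE]
  v <- nv[-nr, , drop = FALSE] & nv[-1L, , drop = FALSE]
  pm <- c(.LAB[["AC"]], .LAB[["PURKINJE"]])
  vm <- c(.LAB[["VM_ENDO"]], .LAB[["VM_MID"]], .LAB[["VM_EPI"]])
  a <- lab[, -nc, drop = FALSE]; b <- lab[, -1L, drop = FALSE]
  h <- h & !(((a %in% pm) & (b %in% vm)) | ((b %in% pm) & (a %in% vm)))
  a <- lab[-nr, , drop = FALSE]; b <- lab[-1L, , drop = FALSE]
  v <- v & !(((a %in% pm) & (b %in% vm)) | ((b %in% pm) & (a %in% vm)))
  list(h = h, v = v)
}

#' Build a 1D chain of automatic cells driving ventricular myocytes
#'
#' A 1 x (n_ac + n_vm) cable: `n_ac` automatic cells (endocardial myocytes
#' with suppressed IK1) followed by `n_vm` unmodified ventricular myocytes,
#' all edges coupled with the normal diffusion coefficient. This is the
#' geometry of the source-sink ("how many ACs drive one VM") experiment.
#'
#' @param n_ac,n_vm Positive cell counts.
#' @param dh Spatial step in mm.
#' @param D Diffusion coefficient in cm^2/ms.
#' @param ac_gk1 IK1 conductance of the ACs in nS/pF.
#' @param vm_type Ventricular variant of the driven cells.
#' @return A [tissue_grid()] with probes `ac1`, `ac_last` and `vm1`.
#' @export
#' @examples
#' g <- build_chain(6, 1)
#' table(g$labels)
build_chain <- function(n_ac, n_vm, dh = .DH_DEFAULT, D = .D_DEFAULT,
                        ac_gk1 = .GK1_AC, vm_type = "ENDO") {
  if (!(n_ac >= 1) || !(n_vm >= 1)) stop("n_ac and n_vm must be >= 1")
  n_ac <- as.integer(n_ac); n_vm <- as.integer(n_vm)
  lab <- matrix(c(rep(.LAB[["AC"]], n_ac), rep(.vm_label(vm_type), n_vm)),
                nrow = 1L)
  probes <- data.frame(name = c("ac1", "ac_last", "vm1"),
                       row = 1L, col = c(1L, n_ac, n_ac + 1L))
  tissue_grid(lab, dh = dh, D = D, ac_gk1 = ac_gk1, probes = probes,
              layout = list(kind = "chain", n_ac = n_ac, n_vm = n_vm,
                            insulated = FALSE))
}

#' Build the insulated pacemaker layout with a Purkinje exit path
#'
#' The engineered pacemaker: an AC block of 5 x 30 computing elements (150
#' cells), a Purkinje-fibre strand of 5 x 50 elements (250 cells, 50 elements
#' x 0.33 mm = 16.5 mm long), and an exit window formed by the distal 5 x 5
#' strand elements (25 cells). The AC block and the strand are electrically
#' insulated from the ventricular myocytes: excitation can reach the working
#' myocardium only through the exit window. The apparatus is attached to the
#' left edge of a rectangular VM sheet standing in for ventricular tissue;
#' unoccupied pixels are VOID.
#'
#' @param vm_rows,vm_cols Size of the hosting VM sheet in pixels; `vm_rows`
#'   must be at least the strand width (5).
#' @param dh,D,ac_gk1,vm_type As in [build_chain()].
#' @return A [tissue_grid()] with layout metadata and probes `ac_center`,
#'   `pk_exit`, `vm_near`, `vm_far`.
#' @export
build_fig2_layout <- function(vm_rows = 100, vm_cols = 100,
                              dh = .DH_DEFAULT, D = .D_DEFAULT,
                              ac_gk1 = .GK1_AC, vm_type = "ENDO") {
  ac_len <- 5L; ac_wid <- 30L        # 150 pacemaker elements
  pk_len <- 50L; pk_wid <- 5L        # 250 strand elements, 16.5 mm
  exit_len <- 5L                     # distal 5 x 5 = 25 exit elements
  if (vm_rows < pk_wid) stop("vm_region too small: need at least ", pk_wid, " rows")
  if (vm_cols < 1L) stop("vm_region too small: need at least 1 column")
  vm_rows <- as.integer(vm_rows); vm_cols <- as.integer(vm_cols)
  nr <- max(ac_wid, vm_rows)
  nc <- ac_len + pk_len + vm_cols
  lab <- matrix(.LAB[["VOID"]], nr, nc)
  ac_r0 <- (nr - ac_wid) %/% 2L + 1L
  pk_r0 <- (nr - pk_wid) %/% 2L + 1L
  vm_r0 <- (nr - vm_rows) %/% 2L + 1L
  ac_rows <- ac_r0:(ac_r0 + ac_wid - 1L)
  pk_rows <- pk_r0:(pk_r0 + pk_wid - 1L)
  lab[ac_rows, 1:ac_len] <- .LAB[["AC"]]
  lab[pk_rows, (ac_len + 1L):(ac_len + pk_len)] <- .LAB[["PURKINJE"]]
  lab[pk_rows, (ac_len + pk_len - exit_len + 1L):(ac_len + pk_len)] <-
    .LAB[["PURKINJE_EXIT"]]
  vm_c0 <- ac_len + pk_len + 1L
  lab[vm_r0:(vm_r0 + vm_rows - 1L), vm_c0:(vm_c0 + vm_cols - 1L)] <-
    .vm_label(vm_type)
  cpl <- .insulated_coupling(lab)
  mid_pk <- pk_rows[(pk_wid + 1L) %/% 2L]
  probes <- data.frame(
    name = c("ac_center", "pk_exit", "vm_near", "vm_far"),
    row = c(ac_rows[(ac_wid + 1L) %/% 2L], mid_pk, mid_pk, mid_pk),
    col = c((ac_len + 1L) %/% 2L + 0L, ac_len + pk_len, vm_c0, nc))
  tissue_grid(lab, dh = dh, D = D, couple = cpl, ac_gk1 = ac_gk1,
              probes = probes,
              layout = list(kind = "fig2", n_ac = ac_len * ac_wid,
                            ac_block = c(length = ac_len, width = ac_wid),
                            purkinje_elements = pk_len * pk_wid,
                            purkinje_length_mm = pk_len * dh,
                            exit_elements = exit_len * pk_wid,
                            insulated = TRUE))
}

#' Build the idealized 400 x 100 sheet with a 1000-cell pacemaker
#'
#' An idealized rectangular ventricular sheet of 400 x 100 myocytes with a
#' 1000-cell AC pacemaker (10 x 100 elements) and a short Purkinje strand
#' (5 elements wide, 7.5 mm long: round(7.5 / dh) = 23 elements at the
#' default spacing) whose distal 5 x 5 elements form the exit window;
#' insulation as in [build_fig2_layout()].
#'
#' @param dh,D,ac_gk1,vm_type As in [build_chain()].
#' @param vm_rows,vm_cols Sheet size in pixels (defaults 100 x 400). The
#'   pacemaker keeps 1000 cells (10 columns x `vm_rows` rows) only at the
#'   default height; at other heights it is 10 columns x `vm_rows` rows.
#' @return A [tissue_grid()].
#' @export
build_fig9_layout <- function(vm_rows = 100, vm_cols = 400,
                              dh = .DH_DEFAULT, D = .D_DEFAULT,
                              ac_gk1 = .GK1_AC, vm_type = "ENDO") {
  pk_wid <- 5L
  if (vm_rows < pk_wid) stop("sheet too small: need at least ", pk_wid, " rows")
  vm_rows <- as.integer(vm_rows); vm_cols <- as.integer(vm_cols)
  ac_len <- 10L; ac_wid <- vm_rows   # 10 x 100 = 1000 pacemaker cells
  pk_len <- as.integer(round(7.5 / dh))  # 23 elements at dh = 0.33 mm
  exit_len <- 5L
  nr <- vm_rows
  nc <- ac_len + pk_len + vm_cols
  lab <- matrix(.LAB[["VOID"]], nr, nc)
  lab[, 1:ac_len] <- .LAB[["AC"]]
  pk_r0 <- (nr - pk_wid) %/% 2L + 1L
  pk_rows <- pk_r0:(pk_r0 + pk_wid - 1L)
  lab[pk_rows, (ac_len + 1L):(ac_len + pk_len)] <- .LAB[["PURKINJE"]]
  lab[pk_rows, (ac_len + pk_len - exit_len + 1L):(ac_len + pk_len)] <-
    .LAB[["PURKINJE_EXIT"]]
  vm_c0 <- ac_len + pk_len + 1L
  lab[, vm_c0:(vm_c0 + vm_cols - 1L)] <- .vm_label(vm_type)
  cpl <- .insulated_coupling(lab)
  mid <- pk_rows[(pk_wid + 1L) %/% 2L]
  probes <- data.frame(
    name = c("ac_center", "pk_exit", "vm_near", "vm_mid", "vm_far"),
    row = c(mid, mid, mid, mid, mid),
    col = c(ac_len %/% 2L, ac_len + pk_len, vm_c0,
            vm_c0 + vm_cols %/% 2L, nc))
  tissue_grid(lab, dh = dh, D = D, couple = cpl, ac_gk1 = ac_gk1,
              probes = probes,
              layout = list(kind = "fig9", n_ac = ac_len * ac_wid,
                            ac_block = c(length = ac_len, width = ac_wid),
                            purkinje_elements = pk_len * pk_wid,
                            purkinje_length_mm = pk_len * dh,
                            exit_elements = exit_len * pk_wid,
                            vm_cells = vm_rows * vm_cols,
                            insulated = TRUE))
}

#' Build a directly coupled AC block inside a VM sheet
#'
#' A contiguous near-square block of `n_ac` automatic cells fully coupled to
#' the surrounding quiescent myocytes, with no insulation: the geometry of
#' the source-sink stalemate experiment, where the hyperpolarizing load of
#' the surrounding tissue suppresses the pacemaker.
#'
#' @param n_ac Number of automatic cells (>= 1); factored into the most
#'   square rectangle with exactly `n_ac` elements.
#' @param vm_rows,vm_cols Size of the hosting VM sheet in pixels.
#' @param dh,D,ac_gk1,vm_type As in [build_chain()].
#' @return A [tissue_grid()] with `layout$insulated = FALSE` and probes
#'   `ac_center`, `vm_near`, `vm_far`.
#' @export
build_direct_block <- function(n_ac, vm_rows = 50, vm_cols = 50,
                               dh = .DH_DEFAULT, D = .D_DEFAULT,
                               ac_gk1 = .GK1_AC, vm_type = "ENDO") {
  if (!(n_ac >= 1)) stop("n_ac must be >= 1")
  n_ac <- as.integer(n_ac)
  vm_rows <- as.integer(vm_rows); vm_cols <- as.integer(vm_cols)
  w <- as.integer(floor(sqrt(n_ac)))
  while (n_ac %% w != 0L) w <- w - 1L
  h <- n_ac %/% w                   # block is h rows x w cols, h >= w
  if (h > vm_rows || w > vm_cols)
    stop("vm_region too small for a block of ", n_ac, " ACs (", h, " x ", w, ")")
  lab <- matrix(.vm_label(vm_type), vm_rows, vm_cols)
  r0 <- (vm_rows - h) %/% 2L + 1L
  c0 <- (vm_cols - w) %/% 2L + 1L
  lab[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- .LAB[["AC"]]
  probes <- data.frame(
    name = c("ac_center", "vm_near", "vm_far"),
    row = c(r0 + (h - 1L) %/% 2L, r0 + (h - 1L) %/% 2L, 1L),
    col = c(c0 + (w - 1L) %/% 2L, min(c0 + w, vm_cols), 1L))
  tissue_grid(lab, dh = dh, D = D, couple = "full", ac_gk1 = ac_gk1,
              probes = probes,
              layout = list(kind = "direct", n_ac = n_ac,
                            ac_block = c(length = w, width = h),
                            insulated = FALSE))
}
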