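#' Labelled 2D tissue grid
#'
#' A tissue grid is a rectangular label matrix (codes from [grid_labels()])
#' with the spatial step `dh`, the diffusion coefficient `D`, and per-edge
#' coupling masks between 4-neighbours. Uncoupled edges carry no diffusive
#' flux (they behave like the zero-flux outer boundary), which is how
#' electrical insulation of the pacemaker and Purkinje regions from the
#' working myocardium is realized.
#'
#' Coupling is stored as two logical matrices: `h_couple[i, j]` couples pixel
#' `(i, j)` with `(i, j + 1)` and `v_couple[i, j]` couples `(i, j)` with
#' `(i + 1, j)`; symmetry is therefore structural. With `couple = "full"`
#' every edge between two non-VOID pixels is coupled.
#'
#' @param labels Integer matrix of label codes (see [grid_labels()]).
#' @param dh Spatial step in mm (default 0.33).
#' @param D Diffusion coefficient in cm^2/ms (default 0.00154).
#' @param couple Either `"full"` or a list with logical matrices `h` (nr x
#'   (nc-1)) and `v` ((nr-1) x nc).
#' @param ac_gk1 Maximal IK1 conductance of AC pixels in nS/pF (default 0.05).
#' @param probes Optional data frame with columns `name`, `row`, `col` naming
#'   pixels whose membrane potential [run_tissue()] records by default.
#' @param layout Optional list of layout metadata attached by the builders.
#' @return An object of class `tissue_grid`.
#' @export
tissue_grid <- function(labels, dh = .DH_DEFAULT, D = .D_DEFAULT,
                        couple = "full", ac_gk1 = .GK1_AC,
                        probes = NULL, layout = NULL) {
  stopifnot(is.matrix(labels))
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (!all(labels %in% .LAB)) stop("unknown label code(s) in grid")
  nr <- nrow(labels); nc <- ncol(labels)
  if (identical(couple, "full")) {
    nv <- labels != .LAB[["VOID"]]
    h <- nv[, -nc, drop = FALSE] & nv[, -1L, drop = FALSE]
    v <- nv[-nr, , drop = FALSE] & nv[-1L, , drop = FALSE]
  } else {
    stopifnot(is.list(couple), is.matrix(couple$h), is.matrix(couple$v))
    h <- couple$h; v <- couple$v
  }
  g <- structure(list(labels = labels, dh = dh, D = D,
                      h_couple = h, v_couple = v,
                      ac_gk1 = ac_gk1, probes = probes, layout = layout),
                 class = "tissue_grid")
  validate_tissue_grid(g)
  g
}

#' Validate the invariants of a tissue grid
#'
#' Checks label codes, coupling-mask dimensions, that no coupled edge touches
#' a VOID pixel, and — for grids whose layout declares `insulated = TRUE` —
#' the insulation invariant: an edge between a pacemaker pixel (AC or
#' Purkinje) and a ventricular myocyte may only be coupled when the pacemaker
#' side is flagged as exit window (`PURKINJE_EXIT`). Deliberately
#' non-insulated geometries (AC-VM chains, the directly coupled block) are
#' exempt from the insulation check.
#'
#' @param grid A [tissue_grid()].
#' @return `grid`, invisibly; errors describe the violated invariant.
#' @export
validate_tissue_grid <- function(grid) {
  stopifnot(inherits(grid, "tissue_grid"))
  lab <- grid$labels
  nr <- nrow(lab); nc <- ncol(lab)
  if (!all(lab %in% .LAB)) stop("unknown label code(s) in grid")
  if (!identical(dim(grid$h_couple), c(nr, max(nc - 1L, 0L))))
    stop("h_couple must be ", nr, " x ", nc - 1L)
  if (!identical(dim(grid$v_couple), c(max(nr - 1L, 0L), nc)))
    stop("v_couple must be ", nr - 1L, " x ", nc)
  if (!(grid$dh > 0)) stop("dh must be positive")
  if (!(grid$D > 0)) stop("D must be positive")
  if (grid$ac_gk1 < 0) stop("ac_gk1 must be >= 0")

  void <- .LAB[["VOID"]]
  a_h <- lab[, -nc, drop = FALSE]; b_h <- lab[, -1L, drop = FALSE]
  a_v <- lab[-nr, , drop = FALSE]; b_v <- lab[-1L, , drop = FALSE]
  if (any(grid$h_couple & (a_h == void | b_h == void)) ||
      any(grid$v_couple & (a_v == void | b_v == void)))
    stop("coupled edge touches a VOID pixel")

  pm <- c(.LAB[["AC"]], .LAB[["PURKINJE"]])           # insulated pacemaker labels
  vm <- c(.LAB[["VM_ENDO"]], .LAB[["VM_MID"]], .LAB[["VM_EPI"]])
  if (isTRUE(grid$layout$insulated)) {
    viol_h <- grid$h_couple &
      (((a_h %in% pm) & (b_h %in% vm)) | ((b_h %in% pm) & (a_h %in% vm)))
    viol_v <- grid$v_couple &
      (((a_v %in% pm) & (b_v %in% vm)) | ((b_v %in% pm) & (a_v %in% vm)))
    if (any(viol_h) || any(viol_v))
      stop("insulation violated: AC/PURKINJE pixel coupled to a VM pixel ",
           "outside the exit window")
  }
  invisible(grid)
}

#' @export
print.tissue_grid <- function(x, ...) {
  tab <- table(factor(x$labels, levels = .LAB, labels = names(.LAB)))
  cat("<tissue_grid> ", nrow(x$labels), " x ", ncol(x$labels),
      " pixels, dh = ", x$dh, " mm, D = ", x$D, " cm^2/ms\n", sep = "")
  print(tab[tab > 0])
  invisible(x)
}

# diffusion prefactor D/dh^2 in 1/ms (D in cm^2/ms, dh in mm; 1 cm^2 = 100 mm^2)
.dcoef <- function(grid) grid$D * 100 / grid$dh^2

#' Discrete diffusion operator on a voltage field
#'
#' Applies the 5-point-stencil Laplacian scaled by `D/dh^2` to a voltage
#' field, honouring the per-edge coupling mask: uncoupled edges and the grid
#' border contribute zero flux (mirrored ghost values), so the operator's sum
#' over the whole grid is exactly zero.
#'
#' @param vm_field Numeric matrix matching the grid dimensions (mV); `NA` is
#'   allowed on VOID pixels.
#' @param grid A [tissue_grid()].
#' @return Matrix of the same shape, in mV/ms.
#' @export
apply_laplacian <- function(vm_field, grid) {
  stopifnot(inherits(grid, "tissue_grid"))
  if (!is.matrix(vm_field) || !identical(dim(vm_field), dim(grid$labels)))
    stop("vm_field dimensions must match the grid (",
         nrow(grid$labels), " x ", ncol(grid$labels), ")")
  nr <- nrow(vm_field); nc <- ncol(vm_field)
  lap <- matrix(0, nr, nc)
  if (nc > 1L) {
    d <- vm_field[, -1L, drop = FALSE] - vm_field[, -nc, drop = FALSE]
    m <- matrix(0, nr, nc - 1L)
    m[grid$h_couple] <- d[grid$h_couple]
    lap[, -nc] <- lap[, -nc, drop = FALSE] + m
    lap[, -1L] <- lap[, -1L, drop = FALSE] - m
  }
  if (nr > 1L) {
    d <- vm_field[-1L, , drop = FALSE] - vm_field[-nr, , drop = FALSE]
    m <- matrix(0, nr - 1L, nc)
    m[grid$v_couple] <- d[grid$v_couple]
    lap[-nr, ] <- lap[-nr, , drop = FALSE] + m
    lap[-1L, ] <- lap[-1L, , drop = FALSE] - m
  }
  .dcoef(grid) * lap
}

# label -> (cell type code, gk1); used when compacting a grid for the solver
.label_model <- function(grid) {
  lab <- grid$labels
  ct <- integer(length(lab)); gk1 <- numeric(length(lab))
  ct[lab == .LAB[["VM_ENDO"]]] <- .CT[["ENDO"]]
  ct[lab == .LAB[["VM_MID"]]]  <- .CT[["MID"]]
  ct[lab == .LAB[["VM_EPI"]]]  <- .CT[["EPI"]]
  ct[lab == .LAB[["AC"]]]      <- .CT[["ENDO"]]
  ct[lab %in% c(.LAB[["PURKINJE"]], .LAB[["PURKINJE_EXIT"]])] <- .CT[["PURKINJE"]]
  gk1[ct %in% c(.CT[["ENDO"]], .CT[["MID"]], .CT[["EPI"]])] <- .GK1_VM
  gk1[lab == .LAB[["AC"]]] <- grid$ac_gk1
  gk1[ct == .CT[["PURKINJE"]]] <- .GK1_PURKINJE
  list(ct = ct, gk1 = gk1)
}

# compact non-VOID pixels into a cell list with 0-based coupled-neighbour
# indices for the compiled solver
.compile_grid <- function(grid) {
  lab <- grid$labels
  nr <- nrow(lab); nc <- ncol(lab)
  idx <- which(lab != .LAB[["VOID"]])        # linear, column-major
  ncell <- length(idx)
  if (ncell == 0L) stop("grid contains no tissue pixels")
  id <- matrix(0L, nr, nc)
  id[idx] <- seq_len(ncell)
  nbr <- matrix(-1L, ncell, 4L)              # up, down, left, right
  if (nc > 1L) {
    w <- which(grid$h_couple, arr.ind = TRUE)
    if (nrow(w)) {
      a <- id[cbind(w[, 1L], w[, 2L])]
      b <- id[cbind(w[, 1L], w[, 2L] + 1L)]
      nbr[cbind(a, 4L)] <- b - 1L
      nbr[cbind(b, 3L)] <- a - 1L
    }
  }
  if (nr > 1L) {
    w <- which(grid$v_couple, arr.ind = TRUE)
    if (nrow(w)) {
      a <- id[cbind(w[, 1L], w[, 2L])]
      b <- id[cbind(w[, 1L] + 1L, w[, 2L])]
      nbr[cbind(a, 2L)] <- b - 1L
      nbr[cbind(b, 1L)] <- a - 1L
    }
  }
  mdl <- .label_model(grid)
  list(idx = idx, id = id, nbr = nbr,
       ct = mdl$ct[idx], gk1 = mdl$gk1[idx], ncell = ncell)
}

#' Serialize a tissue grid to a plain-text file
#'
#' Self-describing text container: header lines `key: value` (dimensions,
#' `dh`, `D`, `ac_gk1`, label legend, 0-based row/col convention), the label
#' matrix as space-separated rows, then the horizontal and vertical edge
#' masks as 0/1 rows. [read_tissue_grid()] restores an identical grid.
#'
#' @param grid A [tissue_grid()].
#' @param path Output file path.
#' @return `path` (write) or the restored `tissue_grid` (read).
#' @export
write_tissue_grid <- function(grid, path) {
  stopifnot(inherits(grid, "tissue_grid"))
  lab <- grid$labels
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ventpace_grid: 1",
           paste0("nrow: ", nrow(lab)),
           paste0("ncol: ", ncol(lab)),
           paste0("dh_mm: ", format(grid$dh, digits = 17)),
           paste0("D_cm2ms: ", format(grid$D, digits = 17)),
           paste0("ac_gk1: ", format(grid$ac_gk1, digits = 17)),
           paste0("insulated: ", as.integer(isTRUE(grid$layout$insulated))),
           paste0("legend: ", paste(names(.LAB), .LAB, sep = "=", collapse = " ")),
           "index_convention: 0-based (row, col), row-major")
  writeLines(hdr, con)
  writeLines("labels:", con)
  writeLines(apply(lab, 1L, paste, collapse = " "), con)
  writeLines("h_couple:", con)
  if (ncol(lab) > 1L)
    writeLines(apply(grid$h_couple + 0L, 1L, paste, collapse = " "), con)
  writeLines("v_couple:", con)
  if (nrow(lab) > 1L)
    writeLines(apply(grid$v_couple + 0L, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_tissue_grid
#' @export
read_tissue_grid <- function(path) {
  ln <- readLines(path)
  if (!startsWith(ln[1L], "ventpace_grid:")) stop("not a ventpace grid file")
  getval <- function(key) {
    i <- grep(paste0("^", key, ": "), ln)[1L]
    sub(paste0("^", key, ": "), "", ln[i])
  }
  nr <- as.integer(getval("nrow")); nc <- as.integer(getval("ncol"))
  dh <- as.numeric(getval("dh_mm")); D <- as.numeric(getval("D_cm2ms"))
  ac_gk1 <- as.numeric(getval("ac_gk1"))
  insulated <- identical(getval("insulated"), "1")
  parse_block <- function(tag, nrows, nc_expect) {
    i <- match(paste0(tag, ":"), ln)
    if (nrows == 0L) return(matrix(integer(0), 0L, nc_expect))
    rows <- ln[(i + 1L):(i + nrows)]
    m <- do.call(rbind, lapply(strsplit(rows, " "), as.integer))
    stopifnot(ncol(m) == nc_expect)
    m
  }
  lab <- parse_block("labels", nr, nc)
  h <- if (nc > 1L) parse_block("h_couple", nr, nc - 1L) == 1L
       else matrix(logical(0), nr, 0L)
  v <- if (nr > 1L) parse_block("v_couple", nr - 1L, nc) == 1L
       else matrix(logical(0), 0L, nc)
  tissue_grid(lab, dh = dh, D = D, couple = list(h = h, v = v),
              ac_gk1 = ac_gk1,
              layout = if (insulated) list(insulated = TRUE))
}
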