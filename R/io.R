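#' Write a discrete solution to CSV
#'
#' Writes two CSV files: nodes (`i`, `j`, reference and deformed positions
#' in mm) and elements (family, end-node indices, rest length, stretch and
#' axial force), each with a header comment recording the configuration
#' hash.
#'
#' @param sol A `cornea_discrete` solution.
#' @param nodes_path,elements_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_solution_csv <- function(sol, nodes_path, elements_path) {
  stopifnot(inherits(sol, "cornea_discrete"))
  net <- sol$network
  nd <- net$nd
  nid <- seq_len(net$nn)
  i <- (nid - 1L) %% (net$N + 1L)
  j <- (nid - 1L) %/% (net$N + 1L)
  nodes <- data.frame(i = i, j = j,
                      X_mm = net$X * nd$length_mm, Y_mm = net$Y * nd$length_mm,
                      x_mm = sol$x_mm, y_mm = sol$y_mm)
  e <- net$el
  elements <- data.frame(
    family = e$family,
    i1 = (e$n1 - 1L) %% (net$N + 1L), j1 = (e$n1 - 1L) %/% (net$N + 1L),
    i2 = (e$n2 - 1L) %% (net$N + 1L), j2 = (e$n2 - 1L) %/% (net$N + 1L),
    rest_length_mm = e$L * nd$length_mm,
    stretch = sol$stretch, force_N = sol$force_N
  )
  hdr <- sprintf("# config_hash: %s", config_hash(sol$config))
  for (it in list(list(nodes, nodes_path), list(elements, elements_path))) {
    con <- file(it[[2]], "w")
    writeLines(hdr, con)
    utils::write.csv(it[[1]], con, row.names = FALSE)
    close(con)
  }
  invisible(c(nodes_path, elements_path))
}

#' Read back a nodes CSV
#' @param path Path written by [write_solution_csv()].
#' @return Data frame of the node table (hash comment skipped).
#' @export
read_solution_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write continuum fields to CSV
#'
#' @param sol A `cornea_continuum` solution.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fields_csv <- function(sol, path) {
  tab <- continuum_fields(sol)
  con <- file(path, "w")
  writeLines(sprintf("# config_hash: %s", config_hash(sol$config)), con)
  utils::write.csv(as.data.frame(tab), con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Write a metrics table to CSV
#'
#' One row per report, with the configuration hash and damage parameters.
#'
#' @param reports A list of [metrics_report()] objects (or a single one).
#' @param configs Matching list of configurations.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_metrics_csv <- function(reports, configs, path) {
  if (inherits(reports, "metrics_report")) reports <- list(reports)
  if (inherits(configs, "cornea_config")) configs <- list(configs)
  rows <- purrr::map2(reports, configs, function(r, cfg) {
    data.frame(config_hash = r$config_hash, Dmax = cfg$Dmax, xi = cfg$xi,
               gamma = cfg$gamma, K2 = cfg$K2 / cfg$K1, K3 = cfg$K3 / cfg$K1,
               AD_mm = r$AD_mm, CCT_mm = r$CCT_mm,
               MAC_per_mm = r$MAC_per_mm, MPC_per_mm = r$MPC_per_mm)
  })
  utils::write.csv(dplyr::bind_rows(rows), path, row.names = FALSE)
  invisible(path)
}

#' Legacy-VTK export of a continuum solution
#'
#' Writes the deformed grid as an ASCII legacy-VTK structured grid with the
#' stress components and energy density as point data, for visualization
#' in ParaView and similar tools.
#'
#' @param sol A `cornea_continuum` solution.
#' @param path Output `.vtk` path.
#' @return Invisibly, the path.
#' @export
write_vtk <- function(sol, path) {
  stopifnot(inherits(sol, "cornea_continuum"))
  tab <- continuum_fields(sol)
  nR <- sol$n_R + 1; nP <- sol$n_Phi + 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("corneamech continuum solution config_hash=%s",
                       config_hash(sol$config)),
               "ASCII", "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", nR, nP),
               sprintf("POINTS %d double", nR * nP)), con)
  writeLines(sprintf("%.10g %.10g 0", tab$x_mm, tab$y_mm), con)
  writeLines(c(sprintf("POINT_DATA %d", nR * nP)), con)
  for (fld in c("T_RR_kPa", "T_RPhi_kPa", "T_PhiPhi_kPa", "W")) {
    writeLines(c(sprintf("SCALARS %s double 1", fld), "LOOKUP_TABLE default",
                 sprintf("%.10g", tab[[fld]])), con)
  }
  invisible(path)
}

#' Small deterministic test fixtures
#'
#' @param kind One of `"tiny_lattice"` (an `N = 2`, `M = 4` network at
#'   baseline parameters), `"unit_cell"` (the four corner nodes and element
#'   rest lengths of a single cell, an isosceles trapezoid for finite `N`),
#'   or `"manufactured_field"` (the shear-like field `r = R`,
#'   `phi = Phi + a R` with closed-form deformation gradient; attribute
#'   `a = 0.01`).
#' @return The fixture object.
#' @export
make_fixture <- function(kind) {
  cfg <- cornea_config(Dmax = 0)
  switch(kind,
    tiny_lattice = build_network(modify_config(cfg, gamma = 2), N = 2),
    unit_cell = {
      geom <- cfg$geometry
      disc <- discretization(4, 20)
      nodes <- build_nodes(geom, disc)
      rl <- rest_lengths(geom, disc)
      j <- disc$M / 2
      list(
        corners = rbind(
          c(nodes$X[1, j], nodes$Y[1, j]), c(nodes$X[1, j + 1], nodes$Y[1, j + 1]),
          c(nodes$X[2, j + 1], nodes$Y[2, j + 1]), c(nodes$X[2, j], nodes$Y[2, j])),
        L1_bottom = rl$L1[1], L1_top = rl$L1[2], L2 = rl$L2, L3 = rl$L3[1])
    },
    manufactured_field = {
      a <- 0.01
      f <- deformation_field(function(R, Phi) R, function(R, Phi) Phi + a * R)
      f$a <- a
      f
    },
    stop("unknown fixture kind: ", kind, call. = FALSE)
  )
}
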