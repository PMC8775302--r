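# Treatment trees: gear designs as nodes, single-modification steps as
# directed edges away from a reference design, each edge carrying a
# delta-selectivity comparison.

SMP_POSITIONS <- c("T", "B")
SMP_SIZES <- c("S", "L")
CODEND_GEOMETRIES <- c("D", "S")

#' A gear design label: SMP variant plus codend geometry
#'
#' The design space is the cross of five square-mesh-panel options — small or
#' large (`S`/`L`) panel at the top or bottom (`T`/`B`) of the extension
#' piece, or no panel (`"NONE"`) — with two codend geometries, diamond
#' (`"D"`) or square (`"S"`) mesh: ten designs in all.
#'
#' @param smp One of `"TS"`, `"TL"`, `"BS"`, `"BL"` (position then size) or
#'   `"NONE"`.
#' @param codend `"D"` (diamond mesh) or `"S"` (square mesh).
#' @return A `gear_design` object.
#' @export
gear_design <- function(smp, codend) {
  smp <- toupper(smp)
  codend <- toupper(codend)
  valid_smp <- c(paste0(rep(SMP_POSITIONS, each = 2), SMP_SIZES), "NONE")
  if (!smp %in% valid_smp) {
    rlang::abort(paste0("invalid SMP spec '", smp, "'; expected one of ",
                        paste(valid_smp, collapse = ", ")))
  }
  if (!codend %in% CODEND_GEOMETRIES) rlang::abort("codend must be 'D' or 'S'")
  structure(list(smp = smp, codend = codend), class = "gear_design")
}

#' @export
format.gear_design <- function(x, ...) {
  paste0(if (x$smp == "NONE") "" else paste0("SMP_", x$smp, "+"), "CD_", x$codend)
}

#' @export
print.gear_design <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Parse a gear design label such as `"SMP_TS+CD_D"` or `"CD_S"`
#'
#' @param label Character label in the `SMP_xx+CD_y` / `CD_y` form.
#' @return A [gear_design()].
#' @export
parse_gear_design <- function(label) {
  parts <- strsplit(toupper(label), "+", fixed = TRUE)[[1]]
  cd <- grep("^CD_", parts, value = TRUE)
  sp <- grep("^SMP_", parts, value = TRUE)
  if (length(cd) != 1 || length(sp) > 1 || length(parts) > 2) {
    rlang::abort(paste0("cannot parse gear design label '", label, "'"))
  }
  gear_design(if (length(sp) == 0) "NONE" else sub("^SMP_", "", sp),
              sub("^CD_", "", cd))
}

#' All ten gear designs in the study space
#'
#' @return A list of [gear_design()] objects (five SMP options times two
#'   codend geometries).
#' @export
all_gear_designs <- function() {
  smps <- c("TS", "TL", "BS", "BL", "NONE")
  out <- list()
  for (s in smps) for (cd in CODEND_GEOMETRIES) {
    out[[length(out) + 1]] <- gear_design(s, cd)
  }
  out
}

#' Atomic design modifications between two gear designs
#'
#' Decomposes the difference between two designs into the four atomic
#' modification types: changing SMP size, changing SMP position, removing
#' (or adding) the SMP, and changing codend mesh geometry. SMP presence, size
#' and position are independent axes; removal counts as one modification
#' regardless of the removed panel's size or position. The count is symmetric
#' in the two arguments.
#'
#' @param a,b [gear_design()] objects.
#' @return Character vector of modifications (empty when identical):
#'   subset of `"change SMP size"`, `"change SMP position"`,
#'   `"remove/add SMP"`, `"change codend geometry"`.
#' @export
enumerate_modifications <- function(a, b) {
  stopifnot(inherits(a, "gear_design"), inherits(b, "gear_design"))
  mods <- character(0)
  if (xor(a$smp == "NONE", b$smp == "NONE")) {
    mods <- c(mods, "remove/add SMP")
  } else if (a$smp != "NONE" && b$smp != "NONE") {
    if (substr(a$smp, 2, 2) != substr(b$smp, 2, 2)) mods <- c(mods, "change SMP size")
    if (substr(a$smp, 1, 1) != substr(b$smp, 1, 1)) mods <- c(mods, "change SMP position")
  }
  if (a$codend != b$codend) mods <- c(mods, "change codend geometry")
  mods
}

#' Build the treatment tree over a set of gear designs
#'
#' Starting from the reference design (the gear in commercial use), every
#' design is connected stepwise: a directed edge runs from a baseline design
#' to a treatment design when the two differ by exactly one atomic
#' modification and the treatment is one modification step farther from the
#' reference (breadth-first depth). Each edge is the site of one
#' delta-selectivity comparison. Nodes are laid out breadth-first from the
#' reference with lexicographic tie-breaking, so the edge ordering is
#' reproducible.
#'
#' @param designs List of [gear_design()] objects (default all ten).
#' @param reference The reference [gear_design()] (default `SMP_TS+CD_D`);
#'   must be among `designs`.
#' @return A `treatment_tree`: list with `nodes` (tibble `label`, `depth`),
#'   `edges` (tibble `baseline`, `treatment`, `modification`), `reference`.
#' @export
build_treatment_tree <- function(designs = all_gear_designs(),
                                 reference = gear_design("TS", "D")) {
  stopifnot(inherits(reference, "gear_design"))
  labels <- vapply(designs, format, character(1))
  if (anyDuplicated(labels)) rlang::abort("duplicate designs")
  ref_label <- format(reference)
  if (!ref_label %in% labels) {
    rlang::abort(paste0("reference design ", ref_label, " not among the designs"))
  }
  n <- length(designs)
  nmods <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    nmods[i, j] <- length(enumerate_modifications(designs[[i]], designs[[j]]))
  }
  # breadth-first depths over the single-modification adjacency
  depth <- rep(NA_integer_, n)
  depth[labels == ref_label] <- 0L
  frontier <- which(labels == ref_label)
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (i in frontier) {
      nb <- which(nmods[i, ] == 1L & is.na(depth))
      depth[nb] <- depth[i] + 1L
      nxt <- c(nxt, nb)
    }
    frontier <- sort(unique(nxt))
  }
  if (anyNA(depth)) {
    rlang::abort(paste0("designs unreachable from the reference by single modifications: ",
                        paste(labels[is.na(depth)], collapse = ", ")))
  }
  ord <- order(depth, labels)
  nodes <- tibble::tibble(label = labels[ord], depth = depth[ord])
  edges <- list()
  for (i in ord) for (j in ord) {
    if (nmods[i, j] == 1L && depth[j] == depth[i] + 1L) {
      edges[[length(edges) + 1]] <- tibble::tibble(
        baseline = labels[i], treatment = labels[j],
        modification = enumerate_modifications(designs[[i]], designs[[j]]))
    }
  }
  edges <- if (length(edges) > 0) {
    dplyr::bind_rows(edges) |> dplyr::arrange(.data$baseline, .data$treatment)
  } else {
    tibble::tibble(baseline = character(0), treatment = character(0),
                   modification = character(0))
  }
  structure(list(nodes = nodes, edges = edges, reference = ref_label),
            class = "treatment_tree")
}

#' @export
print.treatment_tree <- function(x, ...) {
  cat("<treatment_tree> ", nrow(x$nodes), " designs, ", nrow(x$edges),
      " single-modification steps, reference: ", x$reference, "\n", sep = "")
  invisible(x)
}

#' Export a treatment tree as JSON
#'
#' @param tree A [build_treatment_tree()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_treatment_tree <- function(tree, path) {
  stopifnot(inherits(tree, "treatment_tree"))
  jsonlite::write_json(
    list(reference = tree$reference, nodes = tree$nodes, edges = tree$edges),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

panel_delta <- function(dc, mcrs, title) {
  ggplot2::ggplot(dc$curve, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = mcrs, colour = "red", linetype = "dotted") +
    ggplot2::labs(title = title, x = "Length (cm)", y = expression(Delta * r(l))) +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::theme_minimal(base_size = 9)
}

panel_selectivity <- function(band, base_band, ref_band, mcrs, title) {
  p <- ggplot2::ggplot(band, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::geom_vline(xintercept = mcrs, colour = "red", linetype = "dotted") +
    ggplot2::labs(title = title, x = "Length (cm)", y = "r(l)") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(base_band)) {
    p <- p + ggplot2::geom_point(data = base_band,
                                 ggplot2::aes(y = .data$mean),
                                 colour = "blue", size = 0.5)
  }
  if (!is.null(ref_band)) {
    p <- p + ggplot2::geom_line(data = ref_band, ggplot2::aes(y = .data$mean),
                                colour = "darkgreen", linetype = "dashed")
  }
  p
}

panel_catch <- function(rp, ref_rp, mcrs, title) {
  p <- ggplot2::ggplot(rp, ggplot2::aes(x = .data$length_cm)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$n_pop), colour = "black",
                       linetype = "solid", linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$n_retained)) +
    ggplot2::geom_vline(xintercept = mcrs, colour = "red", linetype = "dotted") +
    ggplot2::labs(title = title, x = "Length (cm)", y = "Fish retained") +
    ggplot2::theme_minimal(base_size = 9)
  if (all(c("lo", "hi") %in% names(rp))) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                                  fill = "grey70", alpha = 0.6)
  }
  if (!is.null(ref_rp)) {
    p <- p + ggplot2::geom_line(data = ref_rp, ggplot2::aes(y = .data$n_retained),
                                colour = "darkgreen", linetype = "dashed")
  }
  p
}

#' Render a treatment tree to figure files
#'
#' Writes one vector-graphics (PDF) figure per tree: `panels = "delta"` draws
#' one delta panel per edge (delta curve, CI band, zero line);
#' `"selectivity"` draws one selection-curve panel per node (treatment curve
#' with CI band, baseline as dots, reference dashed); `"catch_profile"` draws
#' the retained population per node against the entering population. The
#' MCRS is drawn as a vertical reference line in every panel.
#'
#' @param tree A [build_treatment_tree()] result.
#' @param ensembles Named list (by design label, e.g. `"SMP_TS+CD_D"`) of
#'   combined-curve ensembles ([combine_ensembles()]); required for every
#'   node of the tree.
#' @param lengths Numeric length grid (cm) on which curves are drawn.
#' @param out Output PDF path.
#' @param panels `"delta"`, `"selectivity"` or `"catch_profile"`.
#' @param mcrs MCRS in cm for the vertical reference line.
#' @param pop A [population_structure()]; required for `"catch_profile"`.
#' @param level Confidence level for bands.
#' @return The output path, invisibly.
#' @export
render_tree <- function(tree, ensembles, lengths, out,
                        panels = c("delta", "selectivity", "catch_profile"),
                        mcrs = 27, pop = NULL, level = 0.95) {
  stopifnot(inherits(tree, "treatment_tree"))
  panels <- match.arg(panels)
  missing_nodes <- setdiff(tree$nodes$label, names(ensembles))
  if (length(missing_nodes) > 0) {
    rlang::abort(paste0("no fitted ensemble supplied for node(s): ",
                        paste(missing_nodes, collapse = ", ")))
  }
  plots <- list()
  if (panels == "delta") {
    for (k in seq_len(nrow(tree$edges))) {
      e <- tree$edges[k, ]
      dc <- delta_curve(ensembles[[e$treatment]], ensembles[[e$baseline]],
                        lengths, level = level)
      plots[[k]] <- panel_delta(dc, mcrs, paste0(e$treatment, " - ", e$baseline,
                                                 "\n(", e$modification, ")"))
    }
  } else if (panels == "selectivity") {
    bands <- lapply(ensembles[tree$nodes$label], curve_band,
                    lengths = lengths, level = level)
    ref_band <- bands[[tree$reference]]
    for (k in seq_len(nrow(tree$nodes))) {
      lab <- tree$nodes$label[k]
      base_lab <- tree$edges$baseline[tree$edges$treatment == lab][1]
      plots[[k]] <- panel_selectivity(
        bands[[lab]], if (!is.na(base_lab)) bands[[base_lab]] else NULL,
        if (lab != tree$reference) ref_band else NULL, mcrs, lab)
    }
  } else {
    if (is.null(pop)) rlang::abort("catch_profile panels require `pop`")
    rps <- lapply(ensembles[tree$nodes$label], function(e) {
      retained_population(pop, e$point, ens = e, level = level)
    })
    ref_rp <- rps[[tree$reference]]
    for (k in seq_len(nrow(tree$nodes))) {
      lab <- tree$nodes$label[k]
      plots[[k]] <- panel_catch(rps[[lab]],
                                if (lab != tree$reference) ref_rp else NULL,
                                mcrs, lab)
    }
  }
  ncol_ <- ceiling(sqrt(length(plots)))
  fig <- patchwork::wrap_plots(plots, ncol = ncol_)
  ggplot2::ggsave(out, fig, width = 3.2 * ncol_,
                  height = 2.6 * ceiling(length(plots) / ncol_),
                  device = grDevices::pdf, limitsize = FALSE)
  invisible(out)
}
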