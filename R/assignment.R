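#' Combine per-guide calls into per-cell perturbation assignments
#'
#' Category scheme:
#' * `unassigned` — no guide called;
#' * `singlet_1ps` — exactly one guide called;
#' * `singlet_2ps` — two or more guides called, all targeting one gene
#'   (the expected state for a cell that received one dual-guide vector);
#' * `doublet` — two or more guides called spanning two or more targets
#'   (incongruous; typically a droplet holding multiple cells).
#'
#' Cells carrying one guide or several guides against the same gene are
#' retained for downstream analysis; doublets and unassigned cells are not.
#' Congruence is judged on the library's `target` column, so two
#' protospacers against the same gene from *different* vectors still count
#' as congruent; give each non-targeting vector a distinct target label if
#' two different NT vectors in one cell should read as a doublet.
#'
#' @param calls Call data frame (see [classify_counts()]); one row per
#'   (cell, guide), every guide present in `lib`.
#' @param lib A [guide_library()].
#' @return Data frame, one row per cell: `cell_barcode`, `called_guides`
#'   (comma-joined, sorted), `n_called`, `category`, `target` (`NA` for
#'   unassigned cells and doublets), `retained_for_analysis`.
#' @export
assign_cells <- function(calls, lib) {
  stopifnot(inherits(lib, "guide_library"))
  unknown <- setdiff(unique(calls$guide_id), lib$guide_id)
  if (length(unknown) > 0)
    stop("call references guide_id absent from library: ", unknown[1])
  if (anyDuplicated(paste(calls$cell_barcode, calls$guide_id, sep = "\r")))
    stop("multiple calls for the same (cell, guide) pair")

  cells <- unique(calls$cell_barcode)
  hits <- calls[calls$expressed, , drop = FALSE]
  tgt <- lib$target[match(hits$guide_id, lib$guide_id)]
  by_cell <- split(seq_len(nrow(hits)), hits$cell_barcode)

  res <- lapply(cells, function(cb) {
    ix <- by_cell[[cb]]
    if (is.null(ix)) {
      return(list(guides = "", n = 0L, category = "unassigned",
                  target = NA_character_, retained = FALSE))
    }
    g <- sort(hits$guide_id[ix])
    targets <- unique(tgt[ix])
    if (length(ix) == 1) {
      list(guides = g, n = 1L, category = "singlet_1ps",
           target = targets, retained = TRUE)
    } else if (length(targets) == 1) {
      list(guides = paste(g, collapse = ","), n = length(ix),
           category = "singlet_2ps", target = targets, retained = TRUE)
    } else {
      list(guides = paste(g, collapse = ","), n = length(ix),
           category = "doublet", target = NA_character_, retained = FALSE)
    }
  })
  data.frame(
    cell_barcode = cells,
    called_guides = vapply(res, `[[`, character(1), "guides"),
    n_called = vapply(res, `[[`, integer(1), "n"),
    category = vapply(res, `[[`, character(1), "category"),
    target = vapply(res, `[[`, character(1), "target"),
    retained_for_analysis = vapply(res, `[[`, logical(1), "retained"),
    stringsAsFactors = FALSE
  )
}

#' Cohort-level assignment summary
#'
#' Fractions per category over all matrix cells, the median total guide
#' UMIs per cell, and per-target retained-cell counts. Because "assigned"
#' is ambiguous when doublets are involved, both conventions are reported:
#' `frac_assigned` (any called guide, doublets included) and
#' `frac_assigned_congruent` (singlets only).
#'
#' @param assignments From [assign_cells()]; must cover exactly the cells
#'   of `m`.
#' @param m Cell x guide count matrix used for the calls.
#' @param umi_denominator `"positive"` (default): median guide UMIs over
#'   cells with at least one guide UMI, the rank-plot convention;
#'   `"all"`: over every cell.
#' @return An `assignment_summary` list.
#' @export
summarize_assignments <- function(assignments, m,
                                  umi_denominator = c("positive", "all")) {
  umi_denominator <- match.arg(umi_denominator)
  if (!setequal(assignments$cell_barcode, rownames(m)) ||
      nrow(assignments) != nrow(m))
    stop("assignments and count matrix cover different cells")
  categories <- c("unassigned", "singlet_1ps", "singlet_2ps", "doublet")
  frac <- vapply(categories,
                 function(k) mean(assignments$category == k), numeric(1))
  stopifnot(abs(sum(frac) - 1) < 1e-12)
  totals <- Matrix::rowSums(m)
  umis <- if (umi_denominator == "positive") totals[totals >= 1] else totals
  retained <- assignments[assignments$retained_for_analysis, , drop = FALSE]
  per_target <- if (nrow(retained) > 0) {
    tab <- table(retained$target)
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  structure(list(
    n_cells = nrow(m),
    frac_by_category = frac,
    frac_assigned = 1 - frac[["unassigned"]],
    frac_assigned_congruent = frac[["singlet_1ps"]] + frac[["singlet_2ps"]],
    median_guide_umis = if (length(umis)) stats::median(umis) else NA_real_,
    umi_denominator = umi_denominator,
    cells_per_target = per_target
  ), class = "assignment_summary")
}

#' @export
print.assignment_summary <- function(x, ...) {
  cat("Assignment summary over", x$n_cells, "cells\n")
  for (k in names(x$frac_by_category))
    cat(sprintf("  %-12s %5.1f%%\n", k, 100 * x$frac_by_category[[k]]))
  cat(sprintf("  assigned (incl. doublets): %.1f%%; congruent only: %.1f%%\n",
              100 * x$frac_assigned, 100 * x$frac_assigned_congruent))
  cat(sprintf("  median guide UMIs per cell (%s): %s\n",
              x$umi_denominator, format(x$median_guide_umis)))
  invisible(x)
}
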