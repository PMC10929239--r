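# Molecular quantification: fluorescence intensity totals, the soma/process
# intensity partition for receptor staining, and double-delta-Ct relative
# expression from qPCR Cq tables.

#' Partition fluorescence intensity between soma and processes
#'
#' Total intensity is the sum over the whole image; soma intensity the sum
#' inside the union of the soma masks (the outlined somas that are
#' "cropped out"); process intensity is the remainder. Percent in
#' processes is `100 * process / (process + soma)`.
#'
#' @param image a single-channel, single-frame [image_stack()] or a
#'   numeric matrix.
#' @param soma_masks a [roi_mask()] or list of them, within image bounds.
#' @return an object of class `IntensityPartition`: list with
#'   `total_intensity`, `soma_intensity`, `process_intensity`,
#'   `percent_in_processes` (`NA` with `undefined = TRUE` when the total
#'   is zero).
#' @export
intensity_partition <- function(image, soma_masks) {
  img <- if (inherits(image, "ImageStack")) {
    if (n_channels(image) != 1L) stop("intensity_partition expects one channel")
    get_frame(image)
  } else image
  if (inherits(soma_masks, "RoiMask")) soma_masks <- list(soma_masks)
  soma_union <- matrix(FALSE, nrow(img), ncol(img))
  for (m in soma_masks) {
    stopifnot(inherits(m, "RoiMask"))
    if (!identical(dim(m$mask), dim(img))) stop("soma mask shape mismatch")
    soma_union <- soma_union | m$mask
  }
  total <- sum(img)
  soma <- sum(img[soma_union])
  process <- total - soma
  structure(list(total_intensity = total, soma_intensity = soma,
                 process_intensity = process,
                 percent_in_processes = if (total > 0) 100 * process / total else NA_real_,
                 undefined = total <= 0),
            class = "IntensityPartition")
}

#' Total field fluorescence intensity
#'
#' Sum and mean of all pixel intensities (arbitrary units), with optional
#' constant background subtraction clamped at zero. No subtraction is
#' applied by default: field totals are reported in raw arbitrary units.
#'
#' @param image a single-channel, single-frame [image_stack()] or matrix.
#' @param background constant to subtract per pixel (default 0).
#' @return list with `sum`, `mean`, `background`.
#' @export
total_field_intensity <- function(image, background = 0) {
  img <- if (inherits(image, "ImageStack")) get_frame(image) else image
  v <- pmax(img - background, 0)
  list(sum = sum(v), mean = mean(v), background = background)
}

#' Relative expression by the double-delta-Ct method
#'
#' Livak quantification: replicate Cq values are averaged per
#' (sample, gene); per sample, delta-Ct is the target Cq minus the
#' reference-gene Cq; per group, delta-delta-Ct is the group mean delta-Ct
#' minus the reference group's mean delta-Ct; fold change is
#' `2^(-ddCt)`, so the reference group is 1.0 by construction. Samples
#' missing the reference gene are excluded with a warning.
#'
#' @param table data frame with columns `sample_id`, `group`, `gene`,
#'   `cq` (one row per replicate well, `cq > 0`).
#' @param reference_group group label defined as fold change 1.0.
#' @param reference_gene housekeeping gene used for standardization
#'   (default `"GAPDH"`); every other gene is treated as a target.
#' @return an object of class `FoldChangeResult`: list with `per_sample`
#'   (data frame `gene`, `sample_id`, `group`, `delta_ct`), `groups`
#'   (data frame `gene`, `group`, `n`, `mean_delta_ct`, `delta_delta_ct`,
#'   `fold_change`), and `reference_group`.
#' @export
ddct_fold_change <- function(table, reference_group, reference_gene = "GAPDH") {
  need <- c("sample_id", "group", "gene", "cq")
  if (!all(need %in% names(table))) {
    stop("qPCR table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(table$cq <= 0)) stop("Cq values must be positive")
  if (!reference_gene %in% table$gene) {
    stop("reference gene '", reference_gene, "' absent from table")
  }
  if (!reference_group %in% table$group) {
    stop("reference group '", reference_group, "' absent from table")
  }
  mean_cq <- stats::aggregate(cq ~ sample_id + group + gene, data = table, FUN = mean)
  ref <- mean_cq[mean_cq$gene == reference_gene,
                 c("sample_id", "group", "cq")]
  names(ref)[3] <- "cq_ref"
  targets <- setdiff(unique(mean_cq$gene), reference_gene)
  if (length(targets) == 0L) stop("no target gene in table")
  per_sample <- NULL
  groups <- NULL
  for (g in targets) {
    tg <- mean_cq[mean_cq$gene == g, c("sample_id", "group", "cq")]
    merged <- merge(tg, ref, by = c("sample_id", "group"), all.x = TRUE)
    missing_ref <- is.na(merged$cq_ref)
    if (any(missing_ref)) {
      warning(sum(missing_ref), " sample(s) lack the reference gene for '",
              g, "' and were excluded: ",
              paste(merged$sample_id[missing_ref], collapse = ", "))
      merged <- merged[!missing_ref, ]
    }
    merged$delta_ct <- merged$cq - merged$cq_ref
    ps <- data.frame(gene = g, merged[, c("sample_id", "group", "delta_ct")])
    gr <- stats::aggregate(delta_ct ~ group, data = merged, FUN = mean)
    names(gr)[2] <- "mean_delta_ct"
    gr$n <- stats::aggregate(delta_ct ~ group, data = merged, FUN = length)$delta_ct
    ref_dct <- gr$mean_delta_ct[gr$group == reference_group]
    if (length(ref_dct) == 0L) {
      stop("reference group has no usable sample for target '", g, "'")
    }
    gr$delta_delta_ct <- gr$mean_delta_ct - ref_dct
    gr$fold_change <- 2^(-gr$delta_delta_ct)
    per_sample <- rbind(per_sample, ps)
    groups <- rbind(groups, data.frame(gene = g,
                                       gr[, c("group", "n", "mean_delta_ct",
                                              "delta_delta_ct", "fold_change")]))
  }
  structure(list(per_sample = per_sample, groups = groups,
                 reference_group = reference_group,
                 reference_gene = reference_gene),
            class = "FoldChangeResult")
}

#' @export
print.FoldChangeResult <- function(x, ...) {
  cat("FoldChangeResult (reference group '", x$reference_group, "', gene '",
      x$reference_gene, "'):\n", sep = "")
  print(x$groups, row.names = FALSE)
  invisible(x)
}
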