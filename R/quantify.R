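# Assign weighted hits to sRNA classes (miRNA, tasiRNA, 20-22 and 23-24 nt
# siRNA) and aggregate to families, precursors and length/base profiles.

#' Assign hits to mature miRNAs/tasiRNAs
#'
#' A hit is assigned to a mature feature when the read is 20--22 nt long,
#' lies on the feature's strand, and its interval is contained within the
#' annotated mature interval padded by 2 nt on each side (the read may not
#' extend more than 2 nt beyond either annotated end).
#'
#' @param hits hits data frame from [align_perfect()].
#' @param annotations annotation data frame; rows with `feature_class` in
#'   `mirna_mature`/`tasirna_mature` are used.
#' @param pad allowed overhang beyond the annotated ends (default 2).
#' @param min_len,max_len read length window (defaults 20 and 22).
#' @return data frame `feature_id`, `feature_class`, `family_id`,
#'   `parent_id`, `count` (summed hit weights; features with no assigned
#'   reads appear with count 0), with attribute `hit_index` (row indices
#'   of `hits` that were assigned somewhere, for overlap accounting).
#' @export
assign_mature <- function(hits, annotations, pad = 2L,
                          min_len = 20L, max_len = 22L) {
  feats <- annotations[annotations$feature_class %in%
                         c("mirna_mature", "tasirna_mature"), , drop = FALSE]
  counts <- stats::setNames(numeric(nrow(feats)), feats$feature_id)
  assigned <- logical(nrow(hits))
  if (nrow(hits) && nrow(feats)) {
    hl <- hits$length
    ok <- hl >= min_len & hl <= max_len
    for (i in seq_len(nrow(feats))) {
      sel <- ok &
        hits$chrom == feats$chrom[i] &
        hits$strand == feats$strand[i] &
        hits$start >= feats$start[i] - pad &
        (hits$start + hl) <= feats$end[i] + pad
      counts[i] <- sum(hits$weight[sel])
      assigned <- assigned | sel
    }
  }
  out <- data.frame(feature_id = feats$feature_id,
                    feature_class = feats$feature_class,
                    family_id = feats$family_id,
                    parent_id = feats$parent_id,
                    count = unname(counts), stringsAsFactors = FALSE)
  attr(out, "hit_index") <- which(assigned)
  out
}

#' Assign hits to transposons as siRNAs, split by length class
#'
#' A 20--24 nt read counts toward a transposon if its interval overlaps
#' the transposon by at least 1 nt on either strand. Length bins 20--22
#' and 23--24 are kept separate; a hit overlapping k transposons
#' contributes weight/k to each.
#'
#' @param hits hits data frame from [align_perfect()].
#' @param annotations annotation data frame; `transposon` rows are used.
#' @return data frame `feature_id`, `sclass`
#'   (`siRNA_20_22`/`siRNA_23_24`), `family_id` (the transposon id),
#'   `count`; zero rows included for unhit transposons. Attribute
#'   `hit_index` as in [assign_mature()].
#' @export
assign_sirna <- function(hits, annotations) {
  tes <- annotations[annotations$feature_class == "transposon", , drop = FALSE]
  grid <- expand.grid(feature_id = tes$feature_id,
                      sclass = c("siRNA_20_22", "siRNA_23_24"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$count <- 0
  assigned <- logical(nrow(hits))
  if (nrow(hits) && nrow(tes)) {
    hl <- hits$length
    ok <- which(hl >= 20L & hl <= 24L)
    if (length(ok)) {
      ov <- matrix(FALSE, nrow = length(ok), ncol = nrow(tes))
      for (i in seq_len(nrow(tes))) {
        ov[, i] <- hits$chrom[ok] == tes$chrom[i] &
          hits$start[ok] < tes$end[i] &
          (hits$start[ok] + hl[ok]) > tes$start[i]
      }
      k <- rowSums(ov)
      cls <- ifelse(hl[ok] <= 22L, "siRNA_20_22", "siRNA_23_24")
      for (i in seq_len(nrow(tes))) {
        sel <- ov[, i] & k > 0L
        if (!any(sel)) next
        w <- hits$weight[ok[sel]] / k[sel]
        for (cl in c("siRNA_20_22", "siRNA_23_24")) {
          row <- grid$feature_id == tes$feature_id[i] & grid$sclass == cl
          grid$count[row] <- grid$count[row] + sum(w[cls[sel] == cl])
        }
      }
      assigned[ok[k > 0L]] <- TRUE
    }
  }
  grid$family_id <- grid$feature_id
  out <- grid[, c("feature_id", "sclass", "family_id", "count")]
  attr(out, "hit_index") <- which(assigned)
  out
}

#' Aggregate per-feature counts into families
#'
#' Family value = sum of member values; total mass is conserved. For
#' siRNAs each transposon is its own family.
#'
#' @param per_feature data frame with `family_id` and `count` (and
#'   optionally `sclass`).
#' @return data frame `family_id`, `sclass` (if present), `count`.
#' @export
aggregate_families <- function(per_feature) {
  if (any(is.na(per_feature$family_id)))
    stop_fmt("feature '%s' lacks a family_id",
             per_feature$feature_id[is.na(per_feature$family_id)][1L])
  keys <- if ("sclass" %in% names(per_feature))
    per_feature[, c("family_id", "sclass")] else per_feature[, "family_id", drop = FALSE]
  agg <- stats::aggregate(per_feature$count, by = as.list(keys), FUN = sum)
  names(agg)[ncol(agg)] <- "count"
  agg[order(agg$family_id), , drop = FALSE] |> `rownames<-`(NULL)
}

#' Sum mature sRNA counts per precursor
#'
#' @param mature_counts data frame from [assign_mature()] (needs
#'   `parent_id` and `count`).
#' @param annotations annotation data frame; precursor ids are validated
#'   against it and precursors with no assigned reads are reported with 0.
#' @return data frame `precursor_id`, `count`.
#' @export
per_precursor_counts <- function(mature_counts, annotations) {
  precursors <- annotations$feature_id[annotations$feature_class %in%
                                         c("mirna_precursor", "tasirna_precursor")]
  bad <- setdiff(mature_counts$parent_id, precursors)
  if (length(bad))
    stop_fmt("dangling parent_id '%s' (no such precursor annotated)", bad[1L])
  sums <- tapply(mature_counts$count, mature_counts$parent_id, sum)
  data.frame(precursor_id = precursors,
             count = unname(ifelse(is.na(sums[precursors]), 0, sums[precursors])),
             stringsAsFactors = FALSE)
}

#' Read length and base-composition profile
#'
#' RPM per read length 18--30 over genome-matching reads, and per
#' (length, position) base frequencies weighted by read count.
#'
#' @param reads collapsed reads data frame (`seq`, `count`) restricted to
#'   genome-matching reads.
#' @param genome_matching_total RPM denominator (weighted genome-matching
#'   read count).
#' @param lengths length range profiled (default 18:30).
#' @return list with `rpm` (named vector per length) and `base_freq`
#'   (list per length of a 4 x length frequency matrix over A,C,G,T;
#'   columns sum to 1 where the length has any reads).
#' @export
length_base_profile <- function(reads, genome_matching_total,
                                lengths = 18:30) {
  if (genome_matching_total <= 0) stop_fmt("genome_matching_total must be > 0")
  len <- nchar(reads$seq)
  rpm <- vapply(lengths, function(L)
    compute_rpm(sum(reads$count[len == L]), genome_matching_total), 0)
  names(rpm) <- lengths
  base_freq <- lapply(lengths, function(L) {
    sel <- which(len == L)
    mat <- matrix(0, 4L, L, dimnames = list(DNA_BASES, NULL))
    if (length(sel)) {
      chars <- strsplit(u2t(reads$seq[sel]), "", fixed = TRUE)
      for (i in seq_along(sel)) {
        idx <- match(chars[[i]], DNA_BASES)
        valid <- !is.na(idx)
        mat[cbind(idx[valid], seq_len(L)[valid])] <-
          mat[cbind(idx[valid], seq_len(L)[valid])] + reads$count[sel[i]]
      }
      tot <- colSums(mat)
      mat <- sweep(mat, 2L, ifelse(tot > 0, tot, 1), "/")
    }
    mat
  })
  names(base_freq) <- lengths
  list(rpm = rpm, base_freq = base_freq)
}

#' Quantify sRNA families from an aligned library
#'
#' Runs mature assignment, siRNA assignment, family aggregation and
#' precursor totals, and converts counts to RPM using the library's
#' genome-matching total. Hits counted both as mature sRNA and as siRNA
#' (overlapping annotations) are reported, not resolved.
#'
#' @param aln result of [align_perfect()] / [process_library()].
#' @param annotations annotation data frame.
#' @return list with `families` (data frame `family_id`, `sclass`, `rpm`,
#'   `count`), `mature`, `sirna`, `precursors` (with `rpm`), and
#'   `double_assigned_weight` (hit weight counted in both classes).
#' @export
quantify_families <- function(aln, annotations) {
  gm <- aln$stats$genome_matching_read_total
  mature <- assign_mature(aln$hits, annotations)
  sirna <- assign_sirna(aln$hits, annotations)
  fam_m <- aggregate_families(transform(
    mature, sclass = ifelse(feature_class == "mirna_mature", "miRNA", "tasiRNA")))
  fam_s <- aggregate_families(sirna)
  families <- rbind(fam_m[, c("family_id", "sclass", "count")],
                    fam_s[, c("family_id", "sclass", "count")])
  families$rpm <- vapply(families$count, compute_rpm, 0,
                         genome_matching_total = gm)
  precursors <- per_precursor_counts(mature, annotations)
  precursors$rpm <- vapply(precursors$count, compute_rpm, 0,
                           genome_matching_total = gm)
  dbl <- intersect(attr(mature, "hit_index"), attr(sirna, "hit_index"))
  list(families = families, mature = mature, sirna = sirna,
       precursors = precursors,
       double_assigned_weight = sum(aln$hits$weight[dbl]))
}
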