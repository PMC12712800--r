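#' Fiducial-point vocabulary
#'
#' The eleven fiducial points delineated by the package, in their canonical
#' within-beat order: seven in the systolic complex (Cs, Ds, Es, Fs, Gs, Ks,
#' Ls) and four in the diastolic complex (Bd, Cd, Dd, Ed).  Es and Bd are
#' shoulder points located from their subsequent valley (Fs and Cd) and are
#' not encoded in the segmentation maps.
#'
#' @return Character vector of the 11 labels in canonical order.
#' @export
fiducial_labels <- function() {
  c("Cs", "Ds", "Es", "Fs", "Gs", "Ks", "Ls", "Bd", "Cd", "Dd", "Ed")
}

#' @rdname fiducial_labels
#' @export
valley_labels <- function() c("Cs", "Fs", "Ks", "Cd", "Ed")

#' @rdname fiducial_labels
#' @export
peak_labels <- function() c("Ds", "Gs", "Ls", "Dd")

#' The fixed index of the 19 segmentation maps
#'
#' Every unique ordered pair of encoded fiducials within each complex gets
#' one interval map: 15 systolic pairs from \{Cs, Ds, Fs, Gs, Ks, Ls\},
#' 3 diastolic pairs from \{Cd, Dd, Ed\}, plus the no-event map SM19.
#' Es and Bd appear in no map.
#'
#' @return A data.frame with columns `sm` (SM01..SM19), `from`, `to`
#'   (fiducial labels, `NA` for SM19) and `complex`
#'   (`"systolic"`, `"diastolic"` or `"none"`).
#' @export
sm_index <- function() {
  sys <- c("Cs", "Ds", "Fs", "Gs", "Ks", "Ls")
  dia <- c("Cd", "Dd", "Ed")
  pair_rows <- function(labs, cx) {
    n <- length(labs)
    from <- character(0); to <- character(0)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      from <- c(from, labs[i]); to <- c(to, labs[j])
    }
    data.frame(from = from, to = to, complex = cx)
  }
  tab <- rbind(pair_rows(sys, "systolic"), pair_rows(dia, "diastolic"),
               data.frame(from = NA_character_, to = NA_character_,
                          complex = "none"))
  tab$sm <- sprintf("SM%02d", seq_len(nrow(tab)))
  tab[, c("sm", "from", "to", "complex")]
}

#' Annotation tables
#'
#' An annotation set is a data.frame with columns `beat` (integer beat
#' index), `label` (one of [fiducial_labels()]) and `sample` (1-based sample
#' index).  Within each beat the present labels must respect the canonical
#' ordering and beats must not overlap in time.
#'
#' @param beat,label,sample Vectors of equal length.
#' @return A validated `scg_annotations` data.frame.
#' @export
scg_annotations <- function(beat, label, sample) {
  ann <- data.frame(beat = as.integer(beat), label = as.character(label),
                    sample = as.integer(sample))
  bad <- setdiff(unique(ann$label), fiducial_labels())
  if (length(bad))
    stop("unknown fiducial label(s): ", paste(bad, collapse = ", "))
  ann <- ann[order(ann$beat, match(ann$label, fiducial_labels())), ]
  rownames(ann) <- NULL
  validate_annotations(ann)
  class(ann) <- c("scg_annotations", "data.frame")
  ann
}

validate_annotations <- function(ann) {
  if (nrow(ann) == 0L) return(invisible(ann))
  ord <- fiducial_labels()
  prev_end <- -Inf
  for (b in unique(ann$beat)) {
    rows <- ann[ann$beat == b, ]
    rows <- rows[order(match(rows$label, ord)), ]
    if (is.unsorted(rows$sample, strictly = TRUE))
      stop("annotation ordering violation in beat ", b,
           ": samples must increase in the canonical label order")
    if (rows$sample[1] <= prev_end)
      stop("beats overlap at beat ", b)
    prev_end <- rows$sample[nrow(rows)]
  }
  invisible(ann)
}

new_segmaps <- function(maps, fs) {
  stopifnot(is.matrix(maps), nrow(maps) == 19L)
  rownames(maps) <- sm_index()$sm
  structure(list(maps = maps, n_samples = ncol(maps), fs = fs),
            class = "scg_segmaps")
}

#' Encode annotations into the 19 binary segmentation maps
#'
#' For each beat and each interval map whose two fiducials are both
#' annotated in that beat, samples in the inclusive range between them are
#' set to 1.  SM19 is the per-sample complement of the union of the 18
#' interval maps.  Pairs with a missing endpoint are skipped; runs are
#' clipped to `[1, n_samples]`.
#'
#' @param annotations An [scg_annotations] table.
#' @param n_samples Length of the signal the maps align to.
#' @param fs Sampling frequency in Hz.
#' @return An `scg_segmaps` object: a 19 x `n_samples` binary matrix plus
#'   metadata.
#' @export
encode_segmaps <- function(annotations, n_samples, fs) {
  validate_annotations(annotations)
  idx <- sm_index()
  maps <- matrix(0, nrow = 19L, ncol = n_samples)
  if (nrow(annotations)) {
    for (b in unique(annotations$beat)) {
      rows <- annotations[annotations$beat == b, ]
      at <- stats::setNames(rows$sample, rows$label)
      for (k in seq_len(18L)) {
        f <- idx$from[k]; t <- idx$to[k]
        if (!is.na(at[f]) && !is.na(at[t])) {
          s0 <- max(1L, at[[f]]); s1 <- min(n_samples, at[[t]])
          if (s0 <= s1) maps[k, s0:s1] <- 1
        }
      }
    }
  }
  maps[19L, ] <- as.numeric(colSums(maps[1:18, , drop = FALSE]) == 0)
  new_segmaps(maps, fs)
}

#' Decode run edges from binary segmentation maps
#'
#' Reports every maximal run of ones in every map with inclusive 1-based
#' endpoints; for ground-truth maps these endpoints are the fiducial
#' samples.
#'
#' @param segmaps An `scg_segmaps` object with binary maps.
#' @return data.frame with columns `sm`, `start`, `end`.
#' @export
decode_edges <- function(segmaps) {
  stopifnot(inherits(segmaps, "scg_segmaps"))
  out <- lapply(seq_len(19L), function(k) {
    r <- runs_of_ones(segmaps$maps[k, ])
    if (nrow(r)) cbind(sm = sm_index()$sm[k], r) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(sm = character(0), start = integer(0),
                                      end = integer(0))
  rownames(out) <- NULL
  out
}

#' Candidate maps for an encoded fiducial label
#'
#' Each encoded fiducial bounds several interval maps; a systolic label
#' bounds exactly five and a diastolic label exactly two.  The returned
#' table says, for each such map, whether the label sits at the run start
#' or the run end.
#'
#' @param label One of the nine encoded labels (not Es or Bd).
#' @return data.frame with columns `sm` and `side` (`"start"`/`"end"`).
#' @export
candidate_maps <- function(label) {
  if (label %in% c("Es", "Bd"))
    stop(label, " is not encoded in the segmentation maps; ",
         "it is located by shoulder detection")
  idx <- sm_index()
  hit <- which(idx$from == label | idx$to == label)
  if (!length(hit)) stop("unknown fiducial label: ", label)
  data.frame(sm = idx$sm[hit],
             side = ifelse(idx$from[hit] == label, "start", "end"))
}

#' @export
print.scg_segmaps <- function(x, ...) {
  cat("<scg_segmaps> 19 x", x$n_samples, "maps, fs =", x$fs, "Hz\n")
  vals <- range(x$maps)
  cat("  values in [", vals[1], ",", vals[2], "]\n")
  invisible(x)
}
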