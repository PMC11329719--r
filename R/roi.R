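#' Region-of-interest name registries
#'
#' The clustering input is a fixed panel of 41 hemisphere-averaged gray-matter
#' features: 34 cortical thickness regions of the Desikan-Killiany parcellation
#' (mm) and 7 subcortical gray-matter volumes (mm^3). Names follow FreeSurfer
#' `aparc`/`aseg` conventions, lower-cased, without hemisphere prefixes.
#'
#' @return Character vector of ROI names.
#' @export
dk_cortical_rois <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
    "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
    "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
    "precentral", "precuneus", "rostralanteriorcingulate",
    "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
    "superiortemporal", "supramarginal", "temporalpole", "transversetemporal")
}

#' @rdname dk_cortical_rois
#' @export
subcortical_rois <- function() {
  c("thalamus", "caudate", "putamen", "pallidum", "hippocampus", "amygdala",
    "accumbens")
}

#' @rdname dk_cortical_rois
#' @export
all_rois <- function() c(dk_cortical_rois(), subcortical_rois())

#' Feature kind (thickness or volume) for each ROI
#'
#' @param rois character vector of ROI names; defaults to the full 41-ROI panel.
#' @return Named character vector, values `"thickness"` or `"volume"`.
#' @export
roi_kind <- function(rois = all_rois()) {
  stopifnot(all(rois %in% all_rois()))
  k <- ifelse(rois %in% dk_cortical_rois(), "thickness", "volume")
  names(k) <- rois
  k
}
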