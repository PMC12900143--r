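#' The 14-channel consumer headset montage
#'
#' Channel labels follow the international 10-20 naming convention (letters
#' encode the region — AF/F frontal, FC fronto-central, T temporal, P
#' parietal, O occipital — odd digits the left hemisphere, even digits the
#' right). 2-D positions are an azimuthal projection of the standard 10-20
#' sphere onto the unit head disk (radius 1 at ear level), symmetrised across
#' homologous left/right pairs. MNI152 coordinates mix study-reported scalp
#' locations (provenance `"reported"`) with entries completed from the
#' standard montage by mirror symmetry or the projected template position
#' (provenance `"standard"`).
#'
#' @return A tibble with columns `label`, `x`, `y` (unit-disk position),
#'   `mni_x`, `mni_y`, `mni_z` (mm) and `provenance`.
#' @export
#' @examples
#' emotiv_montage()
emotiv_montage <- function() {
  m <- tibble::tribble(
    ~label, ~x,      ~y,
    "AF3",  -0.345,  0.767,
    "F7",   -0.931,  0.564,
    "F3",   -0.465,  0.489,
    "FC5",  -0.789,  0.194,
    "T7",   -1.052, -0.193,
    "P7",   -0.716, -0.721,
    "O1",   -0.243, -0.920,
    "O2",    0.243, -0.920,
    "P8",    0.716, -0.721,
    "T8",    1.052, -0.193,
    "FC6",   0.789,  0.194,
    "F4",    0.465,  0.489,
    "F8",    0.931,  0.564,
    "AF4",   0.345,  0.767)
  mni <- tibble::tribble(
    ~label, ~mni_x, ~mni_y, ~mni_z, ~provenance,
    "AF3",  -30,     50,     36,    "standard",  # mirror of reported AF4
    "F7",   -52,     32,      2,    "reported",
    "F3",   -36,     34,     50,    "standard",  # mirror of reported F4
    "FC5",  -52,     12,     34,    "reported",
    "T7",   -64,    -18,      8,    "standard",  # mirror of reported T8
    "P7",   -52,    -73,     12,    "reported",
    "O1",   -29,   -112,      9,    "standard",  # projected template position
    "O2",    30,   -112,      9,    "standard",
    "P8",    52,    -73,     12,    "standard",  # mirror of reported P7
    "T8",    64,    -18,      8,    "reported",
    "FC6",   12,     34,     52,    "reported",
    "F4",    36,     34,     50,    "reported",
    "F8",    52,     32,      2,    "standard",  # mirror of reported F7
    "AF4",   30,     50,     36,    "reported")
  left_join(m, mni, by = "label")
}

#' Look up the MNI152 coordinate of a montage electrode
#'
#' @param label An electrode label present in [emotiv_montage()].
#' @return A named numeric vector `c(x, y, z)` in mm, with attribute
#'   `provenance` (`"reported"` for study-printed scalp coordinates,
#'   `"standard"` otherwise).
#' @export
#' @examples
#' mni_lookup("AF4")
mni_lookup <- function(label) {
  m <- emotiv_montage()
  row <- m[m$label == label, ]
  if (nrow(row) != 1)
    abort(paste0("Unknown electrode label '", label, "'."),
          class = "neuroplay_montage_error")
  structure(c(x = row$mni_x, y = row$mni_y, z = row$mni_z),
            provenance = row$provenance)
}
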