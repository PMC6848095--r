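# Default subtype archetypes.
#
# The five scoliotic sagittal subtypes fall into two groups by their axial
# projection: Group I (types 2 and 4) has a short kyphotic segment (6 +/- 2
# vertebrae) with a mid-thoracic inflection and projects as a loop; Group II
# (types 1, 3 and 5) has a long kyphotic segment (12 +/- 2 vertebrae) with a
# lower-thoracic/upper-lumbar inflection and projects as a lemniscate.  The
# non-scoliotic profile has the longest kyphotic segment (13 vs 4 vertebrae),
# its inflection one level below Group II's, and smaller amplitudes.
#
# Amplitudes are fixed so peak sagittal offsets are typical of unit-height
# spine curves: the anterior (lordotic) apex a few percent of height and the
# T1 landmark posterior to the L5 plumb line by a comparable amount, the
# non-scoliotic profile smaller on both counts.  Within-group spread (segment
# length +/- 1-2 levels, ~10-25% amplitude differences) mirrors the visible
# spread between subtype means.

archetype_table <- function() {
  list(
    type1 = list(group = "GroupII", kyphotic_len = 12L,
                 lordosis_amplitude = 0.045, kyphosis_amplitude = 0.045,
                 axial = "lemniscate", axial_amplitude = 0.10),
    type2 = list(group = "GroupI", kyphotic_len = 6L,
                 lordosis_amplitude = 0.055, kyphosis_amplitude = 0.045,
                 axial = "loop", axial_amplitude = 0.10),
    type3 = list(group = "GroupII", kyphotic_len = 10L,
                 lordosis_amplitude = 0.040, kyphosis_amplitude = 0.040,
                 axial = "lemniscate", axial_amplitude = 0.06),
    type4 = list(group = "GroupI", kyphotic_len = 8L,
                 lordosis_amplitude = 0.050, kyphosis_amplitude = 0.050,
                 axial = "loop", axial_amplitude = 0.15),
    type5 = list(group = "GroupII", kyphotic_len = 13L,
                 lordosis_amplitude = 0.050, kyphosis_amplitude = 0.040,
                 axial = "lemniscate", axial_amplitude = 0.14),
    nonscoliotic = list(group = "NonScoliotic", kyphotic_len = 13L,
                        lordosis_amplitude = 0.030, kyphosis_amplitude = 0.025,
                        axial = "loop", axial_amplitude = 0.0)
  )
}

#' Default sagittal parameters of a subtype archetype
#'
#' Returns the [sagittal_params()] used for the five scoliotic subtype
#' stand-ins (`"type1"` ... `"type5"`) and the non-scoliotic profile
#' (`"nonscoliotic"`).  Types 2 and 4 form Group I (short kyphosis,
#' mid-thoracic inflection); types 1, 3 and 5 form Group II (long kyphosis,
#' thoraco-lumbar inflection); the non-scoliotic profile has a still lower
#' inflection and smaller amplitudes.
#'
#' @param type Archetype name.
#' @param noise_sd,seed Passed through to [sagittal_params()].
#' @return A [sagittal_params()] object.
#' @export
#' @examples
#' archetype_params("type2")$kyphotic_len  # Group I: short kyphotic segment
archetype_params <- function(type = c("type1", "type2", "type3", "type4",
                                      "type5", "nonscoliotic"),
                             noise_sd = 0, seed = 1L) {
  type <- match.arg(type)
  a <- archetype_table()[[type]]
  sagittal_params(
    kyphotic_len = a$kyphotic_len,
    lordotic_len = 17L - a$kyphotic_len,
    kyphosis_amplitude = a$kyphosis_amplitude,
    lordosis_amplitude = a$lordosis_amplitude,
    n_levels = 17L,
    noise_sd = noise_sd,
    seed = seed,
    group_tag = a$group
  )
}

archetype_group <- function(type) {
  archetype_table()[[type]]$group
}
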