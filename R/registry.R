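#' Species registry for the South Georgia flora
#'
#' Metadata for every angiosperm known from South Georgia: family,
#' native/introduced status and, for introduced species, the management
#' class of the island's non-native plant strategy (I: limited populations
#' targeted for eradication; II: potentially detrimental; III: widespread
#' and difficult to control). One extra row represents the
#' *Acaena magellanica*/*A. tenera* species group, under which seedlings
#' that resolve only to the clade are recorded (`n_taxa = 2`).
#'
#' @return A tibble with columns `species`, `family`, `status`
#'   (`"native"`/`"introduced"`), `mgmt_class` (`"I"`, `"II"`, `"III"` or
#'   `NA` for natives) and `n_taxa` (number of Linnean species covered by
#'   the row).
#' @export
sg_species_registry <- function() {
  reg <- tibble::tribble(
    ~species,                      ~family,            ~status,      ~mgmt_class,
    "Acaena magellanica",          "Rosaceae",         "native",     NA,
    "Acaena tenera",               "Rosaceae",         "native",     NA,
    "Achillea millefolium",        "Asteraceae",       "introduced", "I",
    "Achillea ptarmica",           "Asteraceae",       "introduced", "I",
    "Agrostis capillaris",         "Poaceae",          "introduced", "II",
    "Agrostis vinealis",           "Poaceae",          "introduced", "I",
    "Alopecurus magellanicus",     "Poaceae",          "native",     NA,
    "Anthoxanthum odoratum",       "Poaceae",          "introduced", "I",
    "Anthriscus sylvestris",       "Apiaceae",         "introduced", "I",
    "Avenella flexuosa",           "Poaceae",          "introduced", "I",
    "Callitriche antarctica",      "Plantaginaceae",   "native",     NA,
    "Capsella bursa-pastoris",     "Brassicaceae",     "introduced", "I",
    "Cardamine glacialis",         "Brassicaceae",     "introduced", "I",
    "Carex aquatilis",             "Cyperaceae",       "introduced", "I",
    "Carex meridensis",            "Cyperaceae",       "native",     NA,
    "Carex nigra",                 "Cyperaceae",       "introduced", "I",
    "Carex vallis-pulchrae",       "Cyperaceae",       "introduced", "I",
    "Cerastium fontanum",          "Caryophyllaceae",  "introduced", "III",
    "Colobanthus quitensis",       "Caryophyllaceae",  "native",     NA,
    "Colobanthus subulatus",       "Caryophyllaceae",  "native",     NA,
    "Dactylis glomerata",          "Poaceae",          "introduced", "I",
    "Deschampsia antarctica",      "Poaceae",          "native",     NA,
    "Deschampsia cespitosa",       "Poaceae",          "introduced", "I",
    "Deschampsia parvula",         "Poaceae",          "introduced", "II",
    "Elymus repens",               "Poaceae",          "introduced", "I",
    "Empetrum rubrum",             "Ericaceae",        "introduced", "I",
    "Festuca contracta",           "Poaceae",          "native",     NA,
    "Festuca rubra",               "Poaceae",          "introduced", "I",
    "Galium antarcticum",          "Rubiaceae",        "native",     NA,
    "Juncus filiformis",           "Juncaceae",        "introduced", "I",
    "Juncus scheuchzerioides",     "Juncaceae",        "native",     NA,
    "Leptinella scariosa",         "Asteraceae",       "introduced", "I",
    "Lobelia oligophylla",         "Campanulaceae",    "introduced", "I",
    "Luzula congesta",             "Juncaceae",        "introduced", "I",
    "Luzula multiflora",           "Juncaceae",        "introduced", "I",
    "Montia fontana",              "Montiaceae",       "native",     NA,
    "Nardus stricta",              "Poaceae",          "introduced", "I",
    "Phleum alpinum",              "Poaceae",          "native",     NA,
    "Poa annua",                   "Poaceae",          "introduced", "III",
    "Poa flabellata",              "Poaceae",          "native",     NA,
    "Poa pratensis",               "Poaceae",          "introduced", "II",
    "Poa trivialis",               "Poaceae",          "introduced", "II",
    "Ranunculus acris",            "Ranunculaceae",    "introduced", "I",
    "Ranunculus biternatus",       "Ranunculaceae",    "native",     NA,
    "Ranunculus repens",           "Ranunculaceae",    "introduced", "I",
    "Rostkovia magellanica",       "Juncaceae",        "native",     NA,
    "Rumex acetosella",            "Polygonaceae",     "introduced", "I",
    "Rumex crispus",               "Polygonaceae",     "introduced", "I",
    "Sagina procumbens",           "Caryophyllaceae",  "introduced", "I",
    "Scorzoneroides autumnalis",   "Asteraceae",       "introduced", "I",
    "Stellaria media",             "Caryophyllaceae",  "introduced", "I",
    "Taraxacum officinale",        "Asteraceae",       "introduced", "III",
    "Trifolium repens",            "Fabaceae",         "introduced", "I",
    "Tripleurospermum inodorum",   "Asteraceae",       "introduced", "I",
    "Trisetum spicatum",           "Poaceae",          "introduced", "II",
    "Vaccinium vitis-idaea",       "Ericaceae",        "introduced", "I",
    "Veronica serpyllifolia",      "Plantaginaceae",   "introduced", "I"
  )
  reg$n_taxa <- 1L
  group <- tibble::tibble(
    species = "Acaena magellanica/A. tenera",
    family = "Rosaceae", status = "native", mgmt_class = NA_character_,
    n_taxa = 2L
  )
  dplyr::bind_rows(reg, group)
}
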