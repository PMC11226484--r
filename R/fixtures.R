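# Synthetic study cohort.
#
# build_paper_fixture() constructs, fully deterministically and in code, a
# cohort of 100 patients with 475 outpatient medications plus the matched
# knowledge bases. Records carry only attributes (formulary membership,
# exclusion-list membership, equivalence entries, missing fields, flags);
# the engine re-derives every label. Running reconciliation, review and
# switching over the fixture reproduces the study's printed aggregates:
# category counts 88 S0 / 1 S1 / 200 S2 / 8 S3 / 2 S4 / 39 S5 /
# 114 missing product / 8 missing strength / 15 not prescribed; the
# combination-product sub-analysis (23 combinations, 13 resolved to
# mono-products, 9 to combination products); the review rates (31 of 79
# assessable patients with an interaction, 12 of 73 patients aged 65+ with
# a PIM, 3 PRISCUS and 12 FORTA C/D ingredients); the per-drug rows of the
# frequency top list; and the demographics (ages 64/71/80, medications per
# patient 2/4/7 under the type-7 quartile convention, 511 active
# ingredients via the combinations' extra components).
#
# generate_cohort() is the seeded stochastic counterpart for property
# testing: category rates are free parameters and the knowledge base is
# generated alongside the cohort so that every attribute is realized
# structurally, never as a label.

# ---------------------------------------------------------------------------
# drug metadata

.fx_drug <- function(name, amt, unit = "mg", form = "tablet",
                     atc = NA_character_, salt = NA_character_, title = NULL) {
  if (is.null(title)) {
    title <- paste0(toupper(substr(name, 1L, 1L)), substr(name, 2L, nchar(name)))
    if (!is.na(salt)) title <- paste(title, salt)
  }
  list(name = name, salt = salt, amt = amt, unit = unit, form = form,
       atc = atc, title = title)
}

.fx_strength_label <- function(d) paste0(format(d$amt, scientific = FALSE), d$unit)
.fx_hf_name <- function(d) paste(d$title, .fx_strength_label(d), "HSP")
.fx_ex_name <- function(d) paste(d$title, .fx_strength_label(d), "EXT")
.fx_cspec <- function(d, strength = TRUE) {
  key <- if (is.na(d$salt)) d$name else paste0(d$name, "|", d$salt)
  paste0(key, ":", if (strength) paste(d$amt, d$unit) else "NA")
}

# all mono drugs of the fixture; stocked = TRUE puts a product on the formulary
.fx_drugs <- function() {
  d <- list(
    # frequency top-list drugs
    asa          = .fx_drug("acetylsalicylic acid", 100, atc = "B01AC06"),
    tamsulosin   = .fx_drug("tamsulosin", 0.4, form = "retard-capsule", atc = "G04CA02"),
    amlodipine   = .fx_drug("amlodipine", 5, atc = "C08CA01"),
    metoprolol_succ = .fx_drug("metoprolol", 95, form = "retard-tablet",
                               atc = "C07AB02", salt = "succinate"),
    metoprolol_tart = .fx_drug("metoprolol", 50, atc = "C07AB02", salt = "tartrate"),
    metoprolol_ms = .fx_drug("metoprolol", NA, atc = "C07AB02", salt = "succinate",
                             title = "Metoprolol succinate"),
    atorvastatin = .fx_drug("atorvastatin", 40, atc = "C10AA05"),
    ramipril     = .fx_drug("ramipril", 5, atc = "C09AA05"),
    lthyroxine   = .fx_drug("l-thyroxine", 0.1, atc = "H03AA01"),
    colecalciferol = .fx_drug("colecalciferol", 1000, unit = "iu", atc = "A11CC05"),
    simvastatin  = .fx_drug("simvastatin", 40, atc = "C10AA01"),
    torasemide   = .fx_drug("torasemide", 10, atc = "C03CA04"),
    candesartan  = .fx_drug("candesartan", 16, atc = "C09CA06"),
    dipyrone     = .fx_drug("dipyrone", 500, atc = "N02BB02"),
    pantoprazole = .fx_drug("pantoprazole", 40, atc = "A02BC02"),
    metformin    = .fx_drug("metformin", 1000, atc = "A10BA02"),
    bisoprolol   = .fx_drug("bisoprolol", 5, atc = "C07AB07"),
    rosuvastatin = .fx_drug("rosuvastatin", 20, atc = "C10AA07"),
    allopurinol  = .fx_drug("allopurinol", 300, atc = "M04AA01"),
    ibuprofen    = .fx_drug("ibuprofen", 600, atc = "M01AE01"),
    apixaban     = .fx_drug("apixaban", 5, atc = "B01AF02"),
    rivaroxaban  = .fx_drug("rivaroxaban", 20, atc = "B01AF01"),
    omeprazole   = .fx_drug("omeprazole", 20, atc = "A02BC01"),
    omeprazole40 = .fx_drug("omeprazole", 40, atc = "A02BC01"),
    hct          = .fx_drug("hydrochlorothiazide", 12.5, atc = "C03AA03"),
    salbutamol   = .fx_drug("salbutamol", 0.1, form = "inhaler", atc = "R03AC02"),
    insulin_glargine = .fx_drug("insulin glargine", 100, unit = "iu/ml",
                                form = "pen", atc = "A10AE04"),
    empagliflozin = .fx_drug("empagliflozin", 10, atc = "A10BK03"),
    # extra formulary strengths for combination decomposition
    candesartan32 = .fx_drug("candesartan", 32, atc = "C09CA06"),
    hct25        = .fx_drug("hydrochlorothiazide", 25, atc = "C03AA03"),
    enalapril    = .fx_drug("enalapril", 10, atc = "C09AA02"),
    sitagliptin  = .fx_drug("sitagliptin", 50, atc = "A10BH01"),
    valsartan    = .fx_drug("valsartan", 160, atc = "C09CA03"),
    indapamide15 = .fx_drug("indapamide", 1.5, atc = "C03BA11"),
    indapamide25 = .fx_drug("indapamide", 2.5, atc = "C03BA11"),
    nebivolol    = .fx_drug("nebivolol", 5, atc = "C07AB12"),
    perindopril  = .fx_drug("perindopril", 8, atc = "C09AA04"),
    lercanidipine = .fx_drug("lercanidipine", 10, atc = "C08CA13"),
    telmisartan  = .fx_drug("telmisartan", 80, atc = "C09CA07"),
    chlortalidone = .fx_drug("chlortalidone", 12.5, atc = "C03BA04"),
    felodipine   = .fx_drug("felodipine", 5, atc = "C08CA02"),
    thiamine     = .fx_drug("thiamine", 100, atc = "A11DA01"),
    pyridoxine   = .fx_drug("pyridoxine", 50, atc = "A11HA02"),
    cyanocobalamin = .fx_drug("cyanocobalamin", 1, atc = "B03BA01"),
    folicacid    = .fx_drug("folic acid", 5, atc = "B03BB01"),
    # generic-switch fillers
    clopidogrel  = .fx_drug("clopidogrel", 75, atc = "B01AC04"),
    sertraline   = .fx_drug("sertraline", 50, atc = "N06AB06"),
    lisinopril   = .fx_drug("lisinopril", 10, atc = "C09AA03"),
    losartan     = .fx_drug("losartan", 50, atc = "C09CA01"),
    carvedilol   = .fx_drug("carvedilol", 12.5, atc = "C07AG02"),
    furosemide   = .fx_drug("furosemide", 40, atc = "C03CA01"),
    spironolactone = .fx_drug("spironolactone", 25, atc = "C03DA01"),
    gabapentin   = .fx_drug("gabapentin", 300, atc = "N03AX12"),
    pregabalin   = .fx_drug("pregabalin", 75, form = "capsule", atc = "N03AX16"),
    levetiracetam = .fx_drug("levetiracetam", 500, atc = "N03AX14"),
    # stocked fillers (no switch required)
    paracetamol  = .fx_drug("paracetamol", 500, atc = "N02BE01"),
    enoxaparin   = .fx_drug("enoxaparin", 40, form = "syringe", atc = "B01AB05"),
    ondansetron  = .fx_drug("ondansetron", 8, atc = "A04AA01"),
    macrogol     = .fx_drug("macrogol", 13, unit = "g", form = "sachet", atc = "A06AD15"),
    cetirizine   = .fx_drug("cetirizine", 10, atc = "R06AE07"),
    amoxicillin  = .fx_drug("amoxicillin", 500, atc = "J01CA04"),
    prednisolone = .fx_drug("prednisolone", 5, atc = "H02AB06"),
    simeticone   = .fx_drug("simeticone", 80, atc = "A03AX13"),
    budesonide   = .fx_drug("budesonide", 0.2, form = "inhaler", atc = "R03BA02"),
    # exclusion-list case
    carbamazepine = .fx_drug("carbamazepine", 200, form = "retard-tablet", atc = "N03AF01"),
    # equivalence-table case (basal insulin switching table)
    insulin_detemir = .fx_drug("insulin detemir", 100, unit = "iu/ml",
                               form = "pen", atc = "A10AE05"),
    # wholesaler orders without equivalence tables: urologicals (G04) and
    # oral antidiabetics (A10B)
    solifenacin  = .fx_drug("solifenacin", 5, atc = "G04BD08"),
    desfesoterodine = .fx_drug("desfesoterodine", 7, atc = "G04BD13"),
    oxybutynin   = .fx_drug("oxybutynin", 5, atc = "G04BD04"),
    silodosin    = .fx_drug("silodosin", 8, form = "capsule", atc = "G04CA04"),
    alfuzosin    = .fx_drug("alfuzosin", 10, form = "retard-tablet", atc = "G04CA01"),
    semaglutide  = .fx_drug("semaglutide", 1, form = "pen", atc = "A10BJ06"),
    pioglitazone = .fx_drug("pioglitazone", 30, atc = "A10BG03"),
    vildagliptin = .fx_drug("vildagliptin", 50, atc = "A10BH02"),
    # PIM-catalog fillers (not stocked)
    amitriptyline = .fx_drug("amitriptyline", 25, atc = "N06AA09"),
    diazepam     = .fx_drug("diazepam", 5, atc = "N05BA01"),
    digoxin      = .fx_drug("digoxin", 0.2, atc = "C01AA05"),
    doxazosin    = .fx_drug("doxazosin", 4, atc = "C02CA04"),
    clonidine    = .fx_drug("clonidine", 0.15, atc = "C02AC01"),
    dimenhydrinate = .fx_drug("dimenhydrinate", 50, atc = "R06AA02"),
    etoricoxib   = .fx_drug("etoricoxib", 90, atc = "M01AH05"),
    trimipramine = .fx_drug("trimipramine", 25, atc = "N06AA06"),
    moxonidine   = .fx_drug("moxonidine", 0.3, atc = "C02AC05"),
    # other niche drugs not stocked (wholesaler orders)
    ranolazine   = .fx_drug("ranolazine", 375, form = "retard-tablet", atc = "C01EB18"),
    ivabradine   = .fx_drug("ivabradine", 5, atc = "C01EB17"),
    roflumilast  = .fx_drug("roflumilast", 0.5, atc = "R03DX07"),
    tolvaptan    = .fx_drug("tolvaptan", 15, atc = "C03XA01"),
    apremilast   = .fx_drug("apremilast", 30, atc = "L04AA32"),
    dimethylfumarate = .fx_drug("dimethyl fumarate", 240, form = "capsule", atc = "L04AX07"),
    ticagrelor   = .fx_drug("ticagrelor", 90, atc = "B01AC24"),
    vericiguat   = .fx_drug("vericiguat", 2.5, atc = "C01DX22"),
    pirfenidone  = .fx_drug("pirfenidone", 267, atc = "L04AX05"),
    fingolimod   = .fx_drug("fingolimod", 0.5, form = "capsule", atc = "L04AA27"),
    riociguat    = .fx_drug("riociguat", 1, atc = "C02KX05"),
    tafamidis    = .fx_drug("tafamidis", 61, form = "capsule", atc = "N07XX08"),
    obeticholic  = .fx_drug("obeticholic acid", 5, atc = "A05AA04"),
    # incomplete-information fillers
    magnesium    = .fx_drug("magnesium", 150, atc = "A12CC04"),
    iron         = .fx_drug("iron", 100, atc = "B03AA07"),
    omega3       = .fx_drug("omega-3 fatty acids", 1000, form = "capsule", atc = "C10AX06"),
    melatonin    = .fx_drug("melatonin", 2, form = "retard-tablet", atc = "N05CH01"),
    ginkgo       = .fx_drug("ginkgo", 120, atc = "N06DX02"),
    zinc_tab     = .fx_drug("zinc", 25, atc = "A12CB01"),
    glucosamine  = .fx_drug("glucosamine", 750, atc = "M01AX05"),
    tramadol     = .fx_drug("tramadol", NA, atc = "N02AX02"),
    quetiapine   = .fx_drug("quetiapine", NA, atc = "N05AH04"),
    venlafaxine  = .fx_drug("venlafaxine", NA, atc = "N06AX16"),
    prednisolone_ms = .fx_drug("prednisolone", NA, atc = "H02AB06"),
    # not prescribed during the stay
    sildenafil   = .fx_drug("sildenafil", 50, atc = "G04BE03"),
    tadalafil    = .fx_drug("tadalafil", 5, atc = "G04BE08"),
    methotrexate = .fx_drug("methotrexate", 15, atc = "L04AX03"),
    alendronate  = .fx_drug("alendronate", 70, atc = "M05BA04"),
    colchicine   = .fx_drug("colchicine", 0.5, atc = "M04AC01"),
    hydroxychloroquine = .fx_drug("hydroxychloroquine", 200, atc = "P01BA02"),
    naproxen     = .fx_drug("naproxen", 250, atc = "M01AE02")
  )
  d
}

# drug keys whose product is stocked in the hospital formulary
.fx_stocked <- c(
  "asa", "tamsulosin", "amlodipine", "metoprolol_succ", "atorvastatin",
  "ramipril", "lthyroxine", "colecalciferol", "simvastatin", "torasemide",
  "candesartan", "dipyrone", "pantoprazole", "metformin", "bisoprolol",
  "rosuvastatin", "allopurinol", "ibuprofen", "apixaban", "rivaroxaban",
  "hct", "salbutamol", "insulin_glargine", "empagliflozin",
  "candesartan32", "hct25", "enalapril", "sitagliptin", "valsartan",
  "indapamide15", "indapamide25", "nebivolol", "perindopril",
  "lercanidipine", "telmisartan", "chlortalidone", "felodipine",
  "thiamine", "pyridoxine", "cyanocobalamin", "folicacid",
  "clopidogrel", "sertraline", "lisinopril", "losartan", "carvedilol",
  "furosemide", "spironolactone", "gabapentin", "pregabalin",
  "levetiracetam", "paracetamol", "enoxaparin", "ondansetron", "macrogol",
  "cetirizine", "amoxicillin", "prednisolone", "simeticone", "budesonide")

# ---------------------------------------------------------------------------
# knowledge base of the paper fixture

#' Knowledge base of the packaged study fixture
#'
#' Formulary (mono and combination products), the default
#' substitution-exclusion list, the dose-equivalence entries the study names
#' (PPI, statin, basal-insulin tables), a small illustrative interaction
#' table and illustrative PRISCUS/FORTA catalogs. The interaction and PIM
#' tables are synthetic stand-ins for the (unnamed) compendia the study
#' consulted; real deployments supply their own via [kb_load()].
#'
#' @return A [knowledge_base()].
#' @export
paper_kb <- function() {
  d <- .fx_drugs()
  mono <- do.call(rbind, lapply(.fx_stocked, function(k) {
    dd <- d[[k]]
    data.frame(product_name = .fx_hf_name(dd), dosage_form = dd$form,
               atc = dd$atc, components = .fx_cspec(dd),
               stringsAsFactors = FALSE)
  }))
  combos <- data.frame(
    product_name = c("Ezetimib-Simva 10/40 HSP", "Candesartan-HCT 16/12.5 HSP"),
    dosage_form = "tablet",
    atc = c("C10BA02", "C09DA06"),
    components = c("ezetimibe:10 mg;simvastatin:40 mg",
                   "candesartan:16 mg;hydrochlorothiazide:12.5 mg"),
    stringsAsFactors = FALSE)
  equivalence <- data.frame(
    table_id = c("ppi", "statin", "statin", "insulin"),
    source_ingredient = c("omeprazole", "simvastatin",
                          "ezetimibe;simvastatin", "insulin detemir"),
    source_strength = c("20 mg", "40 mg", "10 mg;80 mg", "100 iu/ml"),
    target_ingredient = c("pantoprazole", "rosuvastatin", "rosuvastatin",
                          "insulin glargine"),
    target_strength = c("40 mg", "20 mg", "20 mg", "100 iu/ml"),
    match_level = c(4L, 4L, 4L, 4L),
    stringsAsFactors = FALSE)
  interactions <- data.frame(
    ingredient_a = c("acetylsalicylic acid", "omeprazole", "ramipril"),
    ingredient_b = c("amlodipine", "clopidogrel", "allopurinol"),
    severity = c("moderate", "moderate", "moderate"),
    stringsAsFactors = FALSE)
  pim <- data.frame(
    ingredient = c("oxybutynin", "amitriptyline", "diazepam",
                   "solifenacin", "desfesoterodine", "silodosin", "alfuzosin",
                   "pioglitazone", "digoxin", "doxazosin", "clonidine",
                   "dimenhydrinate", "etoricoxib", "trimipramine", "moxonidine"),
    catalog = c(rep("priscus", 3L), rep("forta", 12L)),
    category = c(rep(NA_character_, 3L), "C", "C", "C", "C", "D", "C", "C",
                 "C", "D", "C", "D", "C"),
    stringsAsFactors = FALSE)
  knowledge_base(formulary = formulary(rbind(mono, combos)),
                 exclusion = default_exclusion_list(),
                 equivalence = equivalence,
                 interactions = interactions,
                 pim = pim)
}

# ---------------------------------------------------------------------------
# medication records of the paper fixture (attributes only, no labels)

# one block of mono records: n records of drug `key` realizing category `cat`
.fx_mono_block <- function(d, key, cat, n) {
  dd <- d[[key]]
  product <- switch(cat,
                    S0 = .fx_hf_name(dd),
                    MP = NA_character_,
                    MS = paste(dd$title, "EXT"),
                    .fx_ex_name(dd))
  data.frame(group = paste0(key, ".", cat), cat = cat,
             product_name = product,
             ingredients = .fx_cspec(dd, strength = cat != "MS"),
             dosage_form = dd$form, atc = dd$atc,
             prescribed = cat != "NP",
             stringsAsFactors = FALSE)[rep(1L, n), , drop = FALSE]
}

# all 475 medication records; `group` is an internal placement handle only
.fx_records <- function() {
  d <- .fx_drugs()
  m <- function(key, cat, n) .fx_mono_block(d, key, cat, n)
  named <- rbind(
    m("asa", "S0", 3), m("asa", "S2", 11), m("asa", "NP", 2), m("asa", "MP", 13),
    m("tamsulosin", "S0", 6), m("tamsulosin", "S2", 11), m("tamsulosin", "MP", 10),
    m("amlodipine", "S0", 2), m("amlodipine", "S2", 12), m("amlodipine", "MP", 7),
    m("metoprolol_succ", "S0", 7), m("metoprolol_succ", "S2", 6),
    m("metoprolol_tart", "S5", 2), m("metoprolol_succ", "MP", 3),
    m("metoprolol_ms", "MS", 1),
    m("atorvastatin", "S2", 9), m("atorvastatin", "MP", 8), m("atorvastatin", "MS", 1),
    m("ramipril", "S2", 8), m("ramipril", "MP", 9),
    m("lthyroxine", "S0", 2), m("lthyroxine", "S2", 7), m("lthyroxine", "MP", 6),
    m("lthyroxine", "NP", 1),
    m("colecalciferol", "S0", 8), m("colecalciferol", "S2", 7),
    m("simvastatin", "S0", 1), m("simvastatin", "S2", 8), m("simvastatin", "MP", 6),
    m("torasemide", "S0", 1), m("torasemide", "S2", 6), m("torasemide", "MP", 7),
    m("torasemide", "MS", 1),
    m("candesartan", "S0", 1), m("candesartan", "S2", 6), m("candesartan", "MP", 7),
    m("dipyrone", "S2", 12), m("dipyrone", "MP", 2),
    m("pantoprazole", "S0", 1), m("pantoprazole", "S2", 10), m("pantoprazole", "MP", 3),
    m("metformin", "S2", 8), m("metformin", "MP", 4),
    m("bisoprolol", "S2", 2), m("bisoprolol", "MP", 7), m("bisoprolol", "NP", 3),
    m("rosuvastatin", "S0", 1), m("rosuvastatin", "S2", 10),
    m("allopurinol", "S2", 5), m("allopurinol", "MP", 4), m("allopurinol", "MS", 1),
    m("ibuprofen", "S0", 1), m("ibuprofen", "MP", 8),
    m("apixaban", "S0", 8),
    m("rivaroxaban", "S0", 8),
    m("omeprazole", "S3", 6), m("omeprazole40", "S4", 1),
    m("hct", "S0", 1), m("hct", "S2", 6),
    m("salbutamol", "S0", 1), m("salbutamol", "S2", 5),
    m("insulin_glargine", "S0", 3), m("insulin_glargine", "S2", 2),
    m("empagliflozin", "S0", 5))
  # two of the salbutamol generics are reported under the alternate name
  alb <- which(named$group == "salbutamol.S2")[1:2]
  named$ingredients[alb] <- sub("^salbutamol", "albuterol", named$ingredients[alb])

  fillers <- rbind(
    m("paracetamol", "S0", 4), m("enoxaparin", "S0", 3), m("ondansetron", "S0", 2),
    m("macrogol", "S0", 3), m("cetirizine", "S0", 2), m("amoxicillin", "S0", 2),
    m("prednisolone", "S0", 2), m("simeticone", "S0", 2), m("folicacid", "S0", 2),
    m("budesonide", "S0", 2),
    m("carbamazepine", "S1", 1),
    m("clopidogrel", "S2", 7), m("sertraline", "S2", 2), m("enalapril", "S2", 3),
    m("lisinopril", "S2", 3), m("losartan", "S2", 3), m("valsartan", "S2", 3),
    m("nebivolol", "S2", 2), m("carvedilol", "S2", 2), m("furosemide", "S2", 3),
    m("spironolactone", "S2", 2), m("gabapentin", "S2", 3), m("pregabalin", "S2", 2),
    m("levetiracetam", "S2", 2),
    m("insulin_detemir", "S3", 1),
    m("solifenacin", "S5", 1), m("desfesoterodine", "S5", 1), m("oxybutynin", "S5", 1),
    m("silodosin", "S5", 1), m("alfuzosin", "S5", 1), m("semaglutide", "S5", 3),
    m("pioglitazone", "S5", 1), m("vildagliptin", "S5", 1),
    m("amitriptyline", "S5", 1), m("diazepam", "S5", 1), m("digoxin", "S5", 1),
    m("doxazosin", "S5", 1), m("clonidine", "S5", 1), m("dimenhydrinate", "S5", 1),
    m("etoricoxib", "S5", 1), m("trimipramine", "S5", 1), m("moxonidine", "S5", 1),
    m("ranolazine", "S5", 1), m("ivabradine", "S5", 2), m("roflumilast", "S5", 1),
    m("tolvaptan", "S5", 1), m("apremilast", "S5", 1), m("dimethylfumarate", "S5", 1),
    m("ticagrelor", "S5", 1), m("vericiguat", "S5", 1), m("pirfenidone", "S5", 1),
    m("fingolimod", "S5", 1), m("riociguat", "S5", 1), m("tafamidis", "S5", 1),
    m("obeticholic", "S5", 1),
    m("magnesium", "MP", 2), m("iron", "MP", 2), m("omega3", "MP", 1),
    m("melatonin", "MP", 1), m("ginkgo", "MP", 1), m("zinc_tab", "MP", 1),
    m("glucosamine", "MP", 1),
    m("prednisolone_ms", "MS", 1), m("tramadol", "MS", 1), m("quetiapine", "MS", 1),
    m("venlafaxine", "MS", 1),
    m("sildenafil", "NP", 2), m("tadalafil", "NP", 1), m("methotrexate", "NP", 1),
    m("alendronate", "NP", 2), m("colchicine", "NP", 1),
    m("hydroxychloroquine", "NP", 1), m("naproxen", "NP", 1))

  combo <- function(group, cat, product, components, n = 1L,
                    form = "tablet", prescribed = TRUE)
    data.frame(group = group, cat = cat, product_name = product,
               ingredients = components, dosage_form = form, atc = NA_character_,
               prescribed = prescribed,
               stringsAsFactors = FALSE)[rep(1L, n), , drop = FALSE]
  combos <- rbind(
    combo("cmb.ezesimva.S0", "S0", "Ezetimib-Simva 10/40 HSP",
          "ezetimibe:10 mg;simvastatin:40 mg", 2),
    combo("cmb.candhct.S0", "S0", "Candesartan-HCT 16/12.5 HSP",
          "candesartan:16 mg;hydrochlorothiazide:12.5 mg", 2),
    combo("cmb.candhct.S2cc", "S2", "Candecor comp 16/12.5 EXT",
          "candesartan:16 mg;hydrochlorothiazide:12.5 mg", 1),
    combo("cmb.candhct32.S2", "S2", "Candesartan-HCT 32/25 EXT",
          "candesartan:32 mg;hydrochlorothiazide:25 mg", 2),
    combo("cmb.enahct.S2", "S2", "Enalapril-HCT 10/25 EXT",
          "enalapril:10 mg;hydrochlorothiazide:25 mg", 2),
    combo("cmb.metsita.S2", "S2", "Metformin-Sita 1000/50 EXT",
          "metformin:1000 mg;sitagliptin:50 mg", 3),
    combo("cmb.valindneb.S2", "S2", "Valsartan-Inda-Nebi EXT",
          "valsartan:160 mg;indapamide:1.5 mg;nebivolol:5 mg", 1),
    combo("cmb.perindlerc.S2", "S2", "Perindopril-Inda-Lerca EXT",
          "perindopril:8 mg;indapamide:2.5 mg;lercanidipine:10 mg", 1),
    combo("cmb.telchlfel.S2", "S2", "Telmisartan-Chlortalidon-Felo EXT",
          "telmisartan:80 mg;chlortalidone:12.5 mg;felodipine:5 mg", 1),
    combo("cmb.vitb.S2", "S2", "Vitamin-B-Komplex EXT",
          "thiamine:100 mg;pyridoxine:50 mg;cyanocobalamin:1 mg;folic acid:5 mg", 1),
    combo("cmb.ezesimva80.S3", "S3", "Ezetimib-Simva 10/80 EXT",
          "ezetimibe:10 mg;simvastatin:80 mg", 1),
    combo("cmb.duodart.S4", "S4", "Duodart 0.5/0.4 EXT",
          "dutasteride:0.5 mg;tamsulosin:0.4 mg", 1, form = "retard-capsule"),
    combo("cmb.duodart.S5", "S5", "Duodart 0.5/0.4 EXT",
          "dutasteride:0.5 mg;tamsulosin:0.4 mg", 1, form = "retard-capsule"),
    combo("cmb.tb.S5", "S5", "Rifa-4-FDC EXT",
          "rifampicin:150 mg;isoniazid:75 mg;pyrazinamide:400 mg;ethambutol:275 mg", 1),
    combo("cmb.cold.S5", "S5", "Grippal Complex EXT",
          "paracetamol:500 mg;phenylephrine:10 mg;dextromethorphan:15 mg;caffeine:30 mg", 1),
    combo("cmb.mineral.S5", "S5", "Mineral Complex EXT",
          "calcium:600 mg;colecalciferol:400 iu;magnesium:150 mg;zinc:10 mg", 1),
    combo("cmb.multivit.MP", "MP", NA_character_,
          "retinol:0.8 mg;ascorbic acid:100 mg;tocopherol:12 mg;zinc:5 mg", 1))
  out <- rbind(named, fillers, combos)
  rownames(out) <- NULL
  out$rec_id <- seq_len(nrow(out))
  out
}

# ---------------------------------------------------------------------------
# patient roster and deterministic record placement

.fx_patients <- function() {
  counts <- c(rep(1L, 21), rep(2L, 5), rep(3L, 23), rep(4L, 2), rep(5L, 23),
              rep(7L, 2), rep(8L, 8), rep(10L, 8), rep(11L, 6), rep(14L, 2))
  young <- c(43, 46, 48, 50, 52, 53, 54, 55, 56, 57, 58, 58, 59, 60, 60, 61,
             61, 62, 62, 62, 63, 63, 63, 63, 64, 64, 64)
  old <- c(65, 65, 65, 66, 66, 66, 67, 67, 67, 68, 68, 68, 68, 69, 69, 69, 69,
           70, 70, 70, 70, 70, 71, 71, 72, 72, 72, 73, 73, 73, 74, 74, 74, 75,
           75, 75, 76, 76, 76, 77, 77, 77, 78, 78, 78, 79, 79, 80, 80, 80, 81,
           81, 82, 82, 83, 83, 84, 84, 85, 85, 86, 86, 87, 87, 88, 88, 89, 89,
           90, 91, 92, 93, 95)
  young_idx <- c(1:20, 22:28)
  ages <- integer(100L)
  ages[young_idx] <- young
  ages[setdiff(1:100, young_idx)] <- old
  dept <- c(rep("urology", 87), rep("general surgery", 8),
            rep("trauma surgery", 4), "internal medicine")
  main_source <- c(rep("interview", 64), rep("medication_list", 21),
                   rep("medical_documents", 15))
  data.frame(patient_id = sprintf("P%03d", 1:100), age = ages,
             department = dept, main_source = main_source,
             n_meds = counts, stringsAsFactors = FALSE)
}

# ingredient names contained in a record (components only, no strengths)
.fx_rec_ings <- function(spec) {
  parts <- strsplit(spec, ";", fixed = TRUE)[[1L]]
  vapply(parts, function(p) {
    p <- sub(":.*$", "", p)
    sub("\\|.*$", "", p)
  }, character(1L), USE.NAMES = FALSE)
}

# Deterministic assignment of the 475 records to the 100 patients.
# Hard constraints: exact per-patient record counts; no patient holds the
# same ingredient twice; interaction-table pairs co-occur only in the
# designated patients; PIM-catalog ingredients only in the designated
# patients aged 65+; not-prescribed records only where >= 2 prescribed
# medications remain (or on single-medication patients).
.fx_place <- function(records, patients) {
  n_pat <- nrow(patients)
  remaining <- patients$n_meds
  ing_sets <- vector("list", n_pat)
  assignment <- integer(nrow(records))
  rec_ings <- lapply(records$ingredients, .fx_rec_ings)
  kb_pairs <- list(c("acetylsalicylic acid", "amlodipine"),
                   c("omeprazole", "clopidogrel"),
                   c("ramipril", "allopurinol"))
  normed <- lapply(rec_ings, norm_ingredient)

  completes_pair <- function(ings, pi) {
    for (pr in kb_pairs) {
      if (any(pr[1L] == ings) && pr[2L] %in% ing_sets[[pi]]) return(TRUE)
      if (any(pr[2L] == ings) && pr[1L] %in% ing_sets[[pi]]) return(TRUE)
    }
    FALSE
  }
  put <- function(ri, pi, allow_pair = FALSE) {
    if (assignment[ri] != 0L) stop("fixture construction: record placed twice")
    if (remaining[pi] <= 0L) stop("fixture construction: patient over capacity")
    if (any(normed[[ri]] %in% ing_sets[[pi]]))
      stop("fixture construction: duplicate ingredient on one patient")
    if (!allow_pair && completes_pair(normed[[ri]], pi))
      stop("fixture construction: unplanned interaction pair")
    assignment[ri] <<- pi
    remaining[pi] <<- remaining[pi] - 1L
    ing_sets[[pi]] <<- c(ing_sets[[pi]], normed[[ri]])
  }
  pool <- function(group_pattern, cats = NULL) {
    idx <- which(grepl(group_pattern, records$group) & assignment == 0L)
    if (!is.null(cats)) idx <- idx[records$cat[idx] %in% cats]
    idx
  }
  take <- function(group_pattern, cats = NULL) {
    idx <- pool(group_pattern, cats)
    if (!length(idx)) stop("fixture construction: pool exhausted for ", group_pattern)
    idx[1L]
  }

  # designated interaction pairs (the only patients with co-occurring pairs)
  for (k in 1:15) {
    pi <- 76L + k
    put(take("^asa\\.", c("S0", "S2", "MP")), pi)
    put(take("^amlodipine\\."), pi, allow_pair = TRUE)
  }
  put(take("^omeprazole40\\.S4"), 92L)
  put(take("^clopidogrel\\.S2"), 92L, allow_pair = TRUE)
  for (pi in 93:98) {
    put(take("^omeprazole\\.S3"), pi)
    put(take("^clopidogrel\\.S2"), pi, allow_pair = TRUE)
  }
  for (pi in 52:60) {
    put(take("^ramipril\\.", c("S2", "MP")), pi)
    put(take("^allopurinol\\."), pi, allow_pair = TRUE)
  }
  # designated PIM carriers (all aged >= 65); three carry two PIM drugs
  put(take("^oxybutynin\\."), 61L); put(take("^digoxin\\."), 61L)
  put(take("^amitriptyline\\."), 62L); put(take("^doxazosin\\."), 62L)
  put(take("^diazepam\\."), 63L); put(take("^clonidine\\."), 63L)
  pim_singles <- c("solifenacin", "desfesoterodine", "silodosin", "alfuzosin",
                   "pioglitazone", "dimenhydrinate", "etoricoxib",
                   "trimipramine", "moxonidine")
  for (k in seq_along(pim_singles))
    put(take(paste0("^", pim_singles[k], "\\.")), 63L + k)
  # not-prescribed records: six as the sole medication of single-medication
  # patients, the rest on high-count patients (>= 2 prescribed remain)
  np_singles <- c("sildenafil", "sildenafil", "tadalafil", "alendronate",
                  "alendronate", "colchicine")
  for (k in seq_along(np_singles))
    put(take(paste0("^", np_singles[k], "\\."), "NP"), k)
  put(take("^asa\\.", "NP"), 75L)
  put(take("^asa\\.", "NP"), 93L)
  put(take("^lthyroxine\\.", "NP"), 76L)
  for (pi in 94:96) put(take("^bisoprolol\\.", "NP"), pi)
  put(take("^methotrexate\\."), 97L)
  put(take("^hydroxychloroquine\\."), 99L)
  put(take("^naproxen\\."), 100L)
  # the overridden combination and its wholesaler twin
  put(take("^cmb\\.duodart\\.S4"), 99L)
  put(take("^cmb\\.duodart\\.S5"), 100L)

  # everything else: most frequent ingredients first, patient with the most
  # free capacity (ties: lowest index) that satisfies all constraints
  left <- which(assignment == 0L)
  freq <- table(unlist(normed))
  key <- vapply(left, function(ri) max(as.integer(freq[normed[[ri]]])), integer(1L))
  left <- left[order(-key, left)]
  for (ri in left) {
    ok <- which(remaining > 0L)
    ok <- ok[vapply(ok, function(pi)
      !any(normed[[ri]] %in% ing_sets[[pi]]) && !completes_pair(normed[[ri]], pi),
      logical(1L))]
    if (!length(ok))
      stop("fixture construction: no feasible patient for record ", ri)
    pi <- ok[order(-remaining[ok], ok)][1L]
    put(ri, pi)
  }
  if (any(remaining != 0L)) stop("fixture construction: capacity not exhausted")
  patients$patient_id[assignment]
}

# ---------------------------------------------------------------------------

#' Build the packaged deterministic study fixture
#'
#' Constructs the 100-patient / 475-medication cohort, its knowledge base
#' ([paper_kb()]) and the two pharmacist override entries, then (by default)
#' runs the full pipeline over it and asserts every expected marginal via
#' [verify_fixture_marginals()]; a non-conforming construction is an error,
#' never silently returned. The construction involves no randomness: repeated
#' calls are identical.
#'
#' @param verify Run the internal marginal verification (default TRUE).
#' @return List of class `paper_fixture` with `sources`, `patients`,
#'   `overrides` (the pipeline inputs) and `kb`.
#' @export
build_paper_fixture <- function(verify = TRUE) {
  records <- .fx_records()
  patients <- .fx_patients()
  records$patient_id <- .fx_place(records, patients)
  ord <- order(match(records$patient_id, patients$patient_id), records$rec_id)
  records <- records[ord, , drop = FALSE]
  sources <- data.frame(
    patient_id = records$patient_id,
    source = patients$main_source[match(records$patient_id, patients$patient_id)],
    product_name = records$product_name,
    ingredients = records$ingredients,
    dosage_form = records$dosage_form,
    atc = records$atc,
    administration_times = "1-0-0",
    prescribed_during_stay = records$prescribed,
    self_medication = FALSE,
    stringsAsFactors = FALSE)
  overrides <- data.frame(
    patient_id = c("P092", "P099"),
    medication = c("Omeprazole 40mg EXT", "Duodart 0.5/0.4 EXT"),
    target_product = c("Pantoprazole 40mg HSP", "Tamsulosin 0.4mg HSP"),
    note = c("PPI dose not on the equivalence table; individual switch to the stocked PPI",
             "combination partner not stocked; tamsulosin mono-product continued"),
    stringsAsFactors = FALSE)
  fx <- structure(list(sources = sources,
                       patients = patients[, c("patient_id", "age", "department")],
                       overrides = overrides,
                       kb = paper_kb()),
                  class = "paper_fixture")
  if (verify) {
    coh <- reconcile(fx$sources, fx$patients)
    rev <- review_report(coh, fx$kb)
    dec <- switch_cohort(coh, fx$kb, fx$overrides)
    chk <- verify_fixture_marginals(coh, dec, rev)
    if (!all(chk$pass))
      stop("paper fixture does not reproduce its marginals:\n",
           paste(utils::capture.output(print(chk[!chk$pass, ])), collapse = "\n"),
           call. = FALSE)
  }
  fx
}

#' Expected marginals of the packaged study fixture
#'
#' @return Data.frame with columns `check` and `expected`.
#' @export
fixture_spec <- function() {
  status <- c(S0 = 88, S1 = 1, S2 = 200, S3 = 8, S4 = 2, S5 = 39,
              MISSING_PRODUCT = 114, MISSING_STRENGTH = 8, NOT_PRESCRIBED = 15,
              SELF_MEDICATION = 0)
  named <- list(  # printed per-drug splits of the frequency top list
    `acetylsalicylic acid` = c(S0 = 3, S2 = 11, NOT_PRESCRIBED = 2, MISSING_PRODUCT = 13),
    tamsulosin = c(S0 = 6, S2 = 11, MISSING_PRODUCT = 10),
    amlodipine = c(S0 = 2, S2 = 12, MISSING_PRODUCT = 7),
    metoprolol = c(S0 = 7, S2 = 6, S5 = 2, MISSING_PRODUCT = 3, MISSING_STRENGTH = 1),
    atorvastatin = c(S2 = 9, MISSING_PRODUCT = 8, MISSING_STRENGTH = 1),
    ramipril = c(S2 = 8, MISSING_PRODUCT = 9),
    `l-thyroxine` = c(S0 = 2, S2 = 7, MISSING_PRODUCT = 6, NOT_PRESCRIBED = 1),
    colecalciferol = c(S0 = 8, S2 = 7),
    simvastatin = c(S0 = 1, S2 = 8, MISSING_PRODUCT = 6),
    torasemide = c(S0 = 1, S2 = 6, MISSING_PRODUCT = 7, MISSING_STRENGTH = 1),
    candesartan = c(S0 = 1, S2 = 6, MISSING_PRODUCT = 7),
    dipyrone = c(S2 = 12, MISSING_PRODUCT = 2),
    pantoprazole = c(S0 = 1, S2 = 10, MISSING_PRODUCT = 3),
    metformin = c(S2 = 8, MISSING_PRODUCT = 4),
    bisoprolol = c(S2 = 2, MISSING_PRODUCT = 7),
    rosuvastatin = c(S0 = 1, S2 = 10),
    allopurinol = c(S2 = 5, MISSING_PRODUCT = 4, MISSING_STRENGTH = 1),
    ibuprofen = c(S0 = 1, MISSING_PRODUCT = 8),
    apixaban = c(S0 = 8), rivaroxaban = c(S0 = 8),
    omeprazole = c(S3 = 6, S4 = 1),
    hydrochlorothiazide = c(S0 = 1, S2 = 6),
    salbutamol = c(S0 = 1, S2 = 5),
    `insulin glargine` = c(S0 = 3, S2 = 2),
    empagliflozin = c(S0 = 5))
  rows <- list(
    c("n_patients", 100), c("n_medications", 475), c("n_active_ingredients", 511),
    lapply(names(status), function(s) c(paste0("status.", s), status[[s]])),
    c("combo.n", 23),
    c("combo.S0", 4), c("combo.S2", 12), c("combo.S3", 1), c("combo.S4", 1),
    c("combo.S5", 4), c("combo.MISSING_PRODUCT", 1),
    c("combo.switched_to_mono", 13), c("combo.resolved_as_combination", 9),
    c("meds_per_patient.q25", 2), c("meds_per_patient.median", 4),
    c("meds_per_patient.q75", 7),
    c("age.q25", 64), c("age.median", 71), c("age.q75", 80),
    c("n_aged_65plus", 73),
    c("review.assessable", 79), c("review.with_ddi", 31),
    c("review.with_pim", 12), c("review.priscus_ingredients", 3),
    c("review.forta_cd_ingredients", 12),
    c("main_source.interview", 64), c("main_source.medication_list", 21),
    c("main_source.medical_documents", 15),
    unlist(lapply(names(named), function(nm)
      lapply(names(named[[nm]]), function(s)
        c(paste0("drug.", nm, ".", s), named[[nm]][[s]]))), recursive = FALSE))
  flat <- list()
  for (r in rows) flat <- c(flat, if (is.list(r)) r else list(r))
  data.frame(check = vapply(flat, `[`, character(1L), 1L),
             expected = as.numeric(vapply(flat, `[`, character(1L), 2L)),
             stringsAsFactors = FALSE)
}

#' Verify the pipeline outputs of the study fixture against its marginals
#'
#' Re-derives every expected aggregate of [fixture_spec()] from actual
#' pipeline outputs and reports expected vs observed per check.
#'
#' @param cohort Reconciled cohort ([reconcile()]).
#' @param decisions Switching decisions ([switch_cohort()]).
#' @param review Review report ([review_report()]).
#' @return Data.frame with columns `check`, `expected`, `observed`, `pass`.
#' @export
verify_fixture_marginals <- function(cohort, decisions, review) {
  spec <- fixture_spec()
  meds <- cohort$medications
  is_combo <- decisions$n_components >= 2L
  cd <- decisions[is_combo, , drop = FALSE]
  per_pat <- as.integer(table(factor(meds$patient_id,
                                     levels = cohort$patients$patient_id)))
  mq <- if (nrow(meds)) quartiles(per_pat) else c(q25 = 0, median = 0, q75 = 0)
  aq <- if (nrow(cohort$patients)) quartiles(cohort$patients$age) else
    c(q25 = 0, median = 0, q75 = 0)
  ms <- table(factor(cohort$patients$main_source, levels = .sources_enum))
  # per-ingredient observed splits over mono records (name level, any salt)
  mono_ing <- vapply(seq_len(nrow(meds)), function(i) {
    cc <- meds$comps[[i]]
    if (nrow(cc) == 1L) cc$ingredient else NA_character_
  }, character(1L))
  drug_count <- function(nm, st)
    sum(!is.na(mono_ing) & mono_ing == nm &
          decisions$status[match(meds$med_id, decisions$med_id)] == st)
  to_mono <- sum(cd$status %in% c("S2", "S3", "S4") & cd$resolution == "mono",
                 na.rm = TRUE)
  to_combo <- sum(cd$status %in% c("S0", "S5") |
                    (cd$status %in% c("S2", "S3", "S4") &
                       cd$resolution == "combination"), na.rm = TRUE)
  observed <- vapply(spec$check, function(ck) {
    if (ck == "n_patients") return(nrow(cohort$patients))
    if (ck == "n_medications") return(nrow(meds))
    if (ck == "n_active_ingredients") return(sum(meds$n_components))
    if (startsWith(ck, "status."))
      return(sum(decisions$status == sub("^status\\.", "", ck)))
    if (ck == "combo.n") return(nrow(cd))
    if (ck == "combo.switched_to_mono") return(to_mono)
    if (ck == "combo.resolved_as_combination") return(to_combo)
    if (startsWith(ck, "combo."))
      return(sum(cd$status == sub("^combo\\.", "", ck)))
    if (ck == "meds_per_patient.q25") return(mq[["q25"]])
    if (ck == "meds_per_patient.median") return(mq[["median"]])
    if (ck == "meds_per_patient.q75") return(mq[["q75"]])
    if (ck == "age.q25") return(aq[["q25"]])
    if (ck == "age.median") return(aq[["median"]])
    if (ck == "age.q75") return(aq[["q75"]])
    if (ck == "n_aged_65plus")
      return(sum(!is.na(cohort$patients$age) & cohort$patients$age >= 65))
    if (ck == "review.assessable") return(review$n_assessable)
    if (ck == "review.with_ddi") return(review$n_with_ddi)
    if (ck == "review.with_pim") return(review$n_with_pim)
    if (ck == "review.priscus_ingredients")
      return(length(unique(review$pim_findings$ingredient[
        review$pim_findings$catalog == "priscus"])))
    if (ck == "review.forta_cd_ingredients")
      return(length(unique(review$pim_findings$ingredient[
        review$pim_findings$catalog == "forta"])))
    if (startsWith(ck, "main_source."))
      return(as.integer(ms[[sub("^main_source\\.", "", ck)]]))
    if (startsWith(ck, "drug.")) {
      rest <- sub("^drug\\.", "", ck)
      st <- sub("^.*\\.", "", rest)
      nm <- sub("\\.[^.]*$", "", rest)
      return(drug_count(nm, st))
    }
    NA_real_
  }, numeric(1L))
  out <- data.frame(check = spec$check, expected = spec$expected,
                    observed = unname(observed), stringsAsFactors = FALSE)
  out$pass <- !is.na(out$observed) & out$observed == out$expected
  out
}

#' Export a fixture as the standard cohort and knowledge-base CSV files
#'
#' Writes `sources.csv`, `patients.csv`, `overrides.csv` and a `kb/`
#' directory ([kb_write()]) so the fixture can be re-run through the
#' file-based pipeline ([run_pipeline()]) or inspected by hand.
#'
#' @param fixture A fixture (default: the packaged study fixture).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
fixtures_export <- function(fixture = build_paper_fixture(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(fixture$sources, file.path(dir, "sources.csv"),
                   row.names = FALSE, na = "", fileEncoding = "UTF-8")
  utils::write.csv(fixture$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE, na = "", fileEncoding = "UTF-8")
  utils::write.csv(fixture$overrides, file.path(dir, "overrides.csv"),
                   row.names = FALSE, na = "", fileEncoding = "UTF-8")
  kb_write(fixture$kb, file.path(dir, "kb"))
  invisible(dir)
}

# ---------------------------------------------------------------------------
# seeded stochastic cohort generator

#' Parameters of the stochastic cohort generator
#'
#' The category probabilities are applied sequentially per medication, in
#' gate-then-cascade order: not prescribed; product name missing; strength
#' missing; exclusion-listed; exact product stocked (S0); generic available
#' (S2); equivalence entry available (S3); otherwise wholesaler (S5). Each
#' is conditional on the previous attributes not firing. The defaults are
#' the rates of the packaged study cohort (e.g. 15/475 not prescribed,
#' 114/460 of the remainder without product name, ...), so the generator's
#' default output is a stochastic replica of the study conditions.
#'
#' @param n_patients Number of patients.
#' @param seed Mandatory integer seed.
#' @param meds_per_patient Pool of per-patient medication counts sampled
#'   with replacement (default: the study's empirical count distribution).
#' @param p_not_prescribed,p_missing_product,p_missing_strength,p_excluded,p_formulary,p_generic,p_equivalence
#'   Sequential conditional probabilities, all in `[0, 1]`.
#' @param p_self_medication Probability that an otherwise prescribed record
#'   is self-medication (default 0, as in the study cohort).
#' @param ddi_pair_density Probability that a concomitant ingredient pair of
#'   some patient is entered into the generated interaction table.
#' @param age_pool Pool of ages sampled with replacement.
#' @return List of class `generator_params`.
#' @export
generator_params <- function(n_patients = 100L,
                             seed,
                             meds_per_patient = .fx_patients()$n_meds,
                             p_not_prescribed = 15 / 475,
                             p_missing_product = 114 / 460,
                             p_missing_strength = 8 / 346,
                             p_excluded = 1 / 338,
                             p_formulary = 88 / 337,
                             p_generic = 200 / 249,
                             p_equivalence = 8 / 49,
                             p_self_medication = 0,
                             ddi_pair_density = 0.02,
                             age_pool = .fx_patients()$age) {
  if (missing(seed) || is.na(seed)) stop("seed is mandatory", call. = FALSE)
  ps <- c(p_not_prescribed, p_missing_product, p_missing_strength, p_excluded,
          p_formulary, p_generic, p_equivalence, p_self_medication,
          ddi_pair_density)
  if (any(ps < 0 | ps > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 meds_per_patient = meds_per_patient,
                 p_not_prescribed = p_not_prescribed,
                 p_missing_product = p_missing_product,
                 p_missing_strength = p_missing_strength,
                 p_excluded = p_excluded, p_formulary = p_formulary,
                 p_generic = p_generic, p_equivalence = p_equivalence,
                 p_self_medication = p_self_medication,
                 ddi_pair_density = ddi_pair_density, age_pool = age_pool),
            class = "generator_params")
}

#' Expected unconditional category rates implied by generator parameters
#' @param params A [generator_params()] object.
#' @return Named numeric vector over the terminal categories.
#' @export
generator_expected_rates <- function(params) {
  p <- params
  rem <- 1
  out <- c(NOT_PRESCRIBED = rem * p$p_not_prescribed)
  rem <- rem - out["NOT_PRESCRIBED"]
  out["SELF_MEDICATION"] <- rem * p$p_self_medication
  rem <- rem - out["SELF_MEDICATION"]
  out["MISSING_PRODUCT"] <- rem * p$p_missing_product
  rem <- rem - out["MISSING_PRODUCT"]
  out["MISSING_STRENGTH"] <- rem * p$p_missing_strength
  rem <- rem - out["MISSING_STRENGTH"]
  out["S1"] <- rem * p$p_excluded
  rem <- rem - out["S1"]
  out["S0"] <- rem * p$p_formulary
  rem <- rem - out["S0"]
  out["S2"] <- rem * p$p_generic
  rem <- rem - out["S2"]
  out["S3"] <- rem * p$p_equivalence
  out["S5"] <- rem - out["S3"]
  out
}

#' Generate a seeded stochastic cohort with a matched knowledge base
#'
#' Every attribute is realized structurally: an "S0" draw creates a
#' formulary product with the medication's own name, an "S2" draw a
#' formulary generic under a different name, an "S3" draw a dose-equivalence
#' entry plus its stocked target, an "S1" draw uses an exclusion-listed
#' ingredient, and so on. The engine therefore re-derives the categories
#' from the knowledge base. Identical parameters (including the seed)
#' reproduce the identical cohort.
#'
#' @param params A [generator_params()] object.
#' @return List with `sources`, `patients`, `overrides` (NULL), `kb`, and
#'   `intended` (the drawn category per medication, for calibration tests).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed)
  p <- params
  n_pat <- p$n_patients
  counts <- sample(p$meds_per_patient, n_pat, replace = TRUE)
  ages <- sample(p$age_pool, n_pat, replace = TRUE)
  pid <- sprintf("G%05d", seq_len(n_pat))
  n <- sum(counts)
  draw <- function(prob) stats::runif(n) < prob
  cat <- rep("S5", n)
  undecided <- rep(TRUE, n)
  stage <- function(cat_name, prob) {
    hit <- undecided & draw(prob)
    cat[hit] <<- cat_name
    undecided[hit] <<- FALSE
  }
  stage("NOT_PRESCRIBED", p$p_not_prescribed)
  stage("SELF_MEDICATION", p$p_self_medication)
  stage("MISSING_PRODUCT", p$p_missing_product)
  stage("MISSING_STRENGTH", p$p_missing_strength)
  stage("S1", p$p_excluded)
  stage("S0", p$p_formulary)
  stage("S2", p$p_generic)
  stage("S3", p$p_equivalence)

  excl <- default_exclusion_list()$ingredient
  ing <- sprintf("drug%05d", seq_len(n))
  ing[cat == "S1"] <- excl[(which(cat == "S1") %% length(excl)) + 1L]
  hf_name <- sprintf("Product %05d HSP", seq_len(n))
  ex_name <- sprintf("Product %05d EXT", seq_len(n))
  alt <- sprintf("alt%05d", seq_len(n))

  product_name <- ex_name
  product_name[cat == "S0"] <- hf_name[cat == "S0"]
  product_name[cat == "MISSING_PRODUCT"] <- NA_character_
  comps <- paste0(ing, ":100 mg")
  comps[cat == "MISSING_STRENGTH"] <- paste0(ing[cat == "MISSING_STRENGTH"], ":NA")
  fm_rows <- list()
  add_fm <- function(name, components)
    fm_rows[[length(fm_rows) + 1L]] <<- data.frame(
      product_name = name, dosage_form = "tablet", atc = NA_character_,
      components = components, stringsAsFactors = FALSE)
  for (i in which(cat %in% c("S0", "S2")))
    add_fm(hf_name[i], paste0(ing[i], ":100 mg"))
  eq_rows <- list()
  for (i in which(cat == "S3")) {
    add_fm(sprintf("Alt %05d HSP", i), paste0(alt[i], ":100 mg"))
    eq_rows[[length(eq_rows) + 1L]] <- data.frame(
      table_id = "generated", source_ingredient = ing[i],
      source_strength = "100 mg", target_ingredient = alt[i],
      target_strength = "100 mg", match_level = 4L, stringsAsFactors = FALSE)
  }
  fm <- if (length(fm_rows)) do.call(rbind, fm_rows) else
    data.frame(product_name = character(), dosage_form = character(),
               atc = character(), components = character(),
               stringsAsFactors = FALSE)
  eq <- if (length(eq_rows)) do.call(rbind, eq_rows) else NULL

  med_patient <- rep(pid, counts)
  src <- sample(.sources_enum, n, replace = TRUE, prob = c(0.64, 0.21, 0.15))
  sources <- data.frame(
    patient_id = med_patient, source = src, product_name = product_name,
    ingredients = comps, dosage_form = "tablet", atc = NA_character_,
    administration_times = "1-0-0",
    prescribed_during_stay = cat != "NOT_PRESCRIBED",
    self_medication = cat == "SELF_MEDICATION", stringsAsFactors = FALSE)
  patients <- data.frame(patient_id = pid, age = ages,
                         department = "urology", stringsAsFactors = FALSE)
  # interaction table over actually co-occurring ingredient pairs
  inter <- list()
  if (p$ddi_pair_density > 0) {
    by_pat <- split(ing[cat != "NOT_PRESCRIBED"],
                    med_patient[cat != "NOT_PRESCRIBED"])
    for (g in by_pat) {
      g <- unique(g)
      if (length(g) < 2L) next
      pr <- utils::combn(g, 2L)
      keep <- stats::runif(ncol(pr)) < p$ddi_pair_density
      if (any(keep))
        inter[[length(inter) + 1L]] <- data.frame(
          ingredient_a = pr[1L, keep], ingredient_b = pr[2L, keep],
          severity = "moderate", stringsAsFactors = FALSE)
    }
  }
  inter <- if (length(inter)) unique(do.call(rbind, inter)) else NULL
  kb <- knowledge_base(formulary = formulary(fm), equivalence = eq,
                       interactions = inter)
  list(sources = sources, patients = patients, overrides = NULL, kb = kb,
       intended = cat)
}
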