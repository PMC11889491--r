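# Taxon pools for the synthetic cohort. One pool taxon = one ASV. Niches:
# vaginal, penile_skin, shared (colonises both), environmental (source of
# introduced taxa: skin/oral/surroundings), contaminant (reagent kitome).

pool_taxon <- function(species, niche, meanlog = 0, sdlog = 1.2) {
  data.frame(species = species, genus = sub(" .*$", "", species),
             niche = niche, meanlog = meanlog, sdlog = sdlog)
}

#' Default taxon pool for the cohort simulator
#'
#' The vaginal pool carries the four CST-defining *Lactobacillus* species
#' plus the common vaginal anaerobes; the penile-skin pool is deliberately
#' richer (more taxa), reflecting the higher alpha diversity of penile skin
#' communities; a small shared pool colonises both niches; environmental
#' taxa (skin, oral, surroundings) feed the introduced category; the
#' contaminant pool is a typical reagent "kitome".
#'
#' @return data.frame with columns `asv_id`, `species`, `genus`, `niche`,
#'   `meanlog`, `sdlog`.
#' @export
default_niche_pool <- function() {
  vaginal <- c(
    "Lactobacillus crispatus", "Lactobacillus gasseri",
    "Lactobacillus iners", "Lactobacillus jensenii",
    "Gardnerella vaginalis", "Fannyhessea vaginae",
    "Prevotella bivia", "Prevotella corporis", "Sneathia amnii",
    "Megasphaera lornae", "Mobiluncus mulieris",
    "Dialister micraerophilus", "Atopobium deltae",
    "Limosilactobacillus vaginalis")
  penile <- c(
    "Corynebacterium glucuronolyticum", "Corynebacterium tuberculostearicum",
    "Corynebacterium amycolatum", "Staphylococcus epidermidis",
    "Staphylococcus hominis", "Staphylococcus haemolyticus",
    "Finegoldia magna", "Peptoniphilus harei", "Peptoniphilus lacrimalis",
    "Anaerococcus prevotii", "Anaerococcus obesiensis",
    "Cutibacterium acnes", "Enterococcus faecalis", "Streptococcus mitis",
    "Streptococcus agalactiae", "Micrococcus luteus", "Dermabacter hominis",
    "Ezakiella peruensis", "Murdochiella asaccharolytica",
    "Campylobacter ureolyticus", "Negativicoccus succinicivorans",
    "Varibaculum cambriense", "Dialister propionicifaciens",
    "Prevotella disiens")
  shared <- c(
    "Streptococcus anginosus", "Prevotella timonensis",
    "Corynebacterium aurimucosum", "Staphylococcus lugdunensis",
    "Actinomyces neuii", "Veillonella parvula")
  environmental <- c(
    "Rothia mucilaginosa", "Streptococcus salivarius",
    "Haemophilus parainfluenzae", "Neisseria subflava",
    "Moraxella osloensis", "Acinetobacter lwoffii",
    "Kocuria palustris", "Pseudomonas fluorescens")
  contaminant <- c(
    "Ralstonia pickettii", "Bradyrhizobium japonicum",
    "Methylobacterium radiotolerans", "Delftia acidovorans",
    "Burkholderia cepacia")
  pool <- rbind(
    pool_taxon(vaginal, "vaginal"),
    pool_taxon(penile, "penile_skin"),
    pool_taxon(shared, "shared"),
    pool_taxon(environmental, "environmental"),
    pool_taxon(contaminant, "contaminant"))
  pool$asv_id <- sprintf("ASV%03d", seq_len(nrow(pool)))
  pool[, c("asv_id", "species", "genus", "niche", "meanlog", "sdlog")]
}

# Coarse lineage lookups so simulated taxonomy tables look like real ones;
# ranks without an entry fall back to the "unclassified" sentinel.
genus_family <- c(
  Lactobacillus = "Lactobacillaceae", Limosilactobacillus = "Lactobacillaceae",
  Gardnerella = "Bifidobacteriaceae", Fannyhessea = "Atopobiaceae",
  Atopobium = "Atopobiaceae", Prevotella = "Prevotellaceae",
  Sneathia = "Leptotrichiaceae", Megasphaera = "Veillonellaceae",
  Mobiluncus = "Actinomycetaceae", Dialister = "Veillonellaceae",
  Corynebacterium = "Corynebacteriaceae", Staphylococcus = "Staphylococcaceae",
  Finegoldia = "Peptoniphilaceae", Peptoniphilus = "Peptoniphilaceae",
  Anaerococcus = "Peptoniphilaceae", Cutibacterium = "Propionibacteriaceae",
  Enterococcus = "Enterococcaceae", Streptococcus = "Streptococcaceae",
  Micrococcus = "Micrococcaceae", Dermabacter = "Dermabacteraceae",
  Ezakiella = "Peptoniphilaceae", Murdochiella = "Peptoniphilaceae",
  Campylobacter = "Campylobacteraceae", Negativicoccus = "Veillonellaceae",
  Varibaculum = "Actinomycetaceae", Actinomyces = "Actinomycetaceae",
  Veillonella = "Veillonellaceae", Rothia = "Micrococcaceae",
  Haemophilus = "Pasteurellaceae", Neisseria = "Neisseriaceae",
  Moraxella = "Moraxellaceae", Acinetobacter = "Moraxellaceae",
  Kocuria = "Micrococcaceae", Pseudomonas = "Pseudomonadaceae",
  Ralstonia = "Burkholderiaceae", Bradyrhizobium = "Xanthobacteraceae",
  Methylobacterium = "Methylobacteriaceae", Delftia = "Comamonadaceae",
  Burkholderia = "Burkholderiaceae", Listeria = "Listeriaceae",
  Salmonella = "Enterobacteriaceae", Escherichia = "Enterobacteriaceae",
  Bacillus = "Bacillaceae")

genus_phylum <- c(
  Lactobacillus = "Firmicutes", Limosilactobacillus = "Firmicutes",
  Gardnerella = "Actinobacteriota", Fannyhessea = "Actinobacteriota",
  Atopobium = "Actinobacteriota", Prevotella = "Bacteroidota",
  Sneathia = "Fusobacteriota", Megasphaera = "Firmicutes",
  Mobiluncus = "Actinobacteriota", Dialister = "Firmicutes",
  Corynebacterium = "Actinobacteriota", Staphylococcus = "Firmicutes",
  Finegoldia = "Firmicutes", Peptoniphilus = "Firmicutes",
  Anaerococcus = "Firmicutes", Cutibacterium = "Actinobacteriota",
  Enterococcus = "Firmicutes", Streptococcus = "Firmicutes",
  Micrococcus = "Actinobacteriota", Dermabacter = "Actinobacteriota",
  Ezakiella = "Firmicutes", Murdochiella = "Firmicutes",
  Campylobacter = "Campylobacterota", Negativicoccus = "Firmicutes",
  Varibaculum = "Actinobacteriota", Actinomyces = "Actinobacteriota",
  Veillonella = "Firmicutes", Rothia = "Actinobacteriota",
  Haemophilus = "Proteobacteria", Neisseria = "Proteobacteria",
  Moraxella = "Proteobacteria", Acinetobacter = "Proteobacteria",
  Kocuria = "Actinobacteriota", Pseudomonas = "Proteobacteria",
  Ralstonia = "Proteobacteria", Bradyrhizobium = "Proteobacteria",
  Methylobacterium = "Proteobacteria", Delftia = "Proteobacteria",
  Burkholderia = "Proteobacteria", Listeria = "Firmicutes",
  Salmonella = "Proteobacteria", Escherichia = "Proteobacteria",
  Bacillus = "Firmicutes")

# Build a taxonomy table for a set of (asv_id, species) pairs.
make_taxonomy <- function(asv_id, species) {
  genus <- sub(" .*$", "", species)
  data.frame(
    asv_id = asv_id,
    kingdom = "Bacteria",
    phylum = unname(ifelse(genus %in% names(genus_phylum),
                           genus_phylum[genus], "unclassified")),
    class = "unclassified",
    order = "unclassified",
    family = unname(ifelse(genus %in% names(genus_family),
                           genus_family[genus], "unclassified")),
    genus = genus,
    species = species)
}

# The eight bacteria of the standard 8-species mock community.
mock_taxa <- c(
  "Staphylococcus aureus", "Listeria monocytogenes", "Salmonella enterica",
  "Enterococcus faecalis", "Escherichia coli", "Bacillus subtilis",
  "Pseudomonas aeruginosa", "Lactobacillus fermentum")

#' Observed mock-community composition of the reference protocol
#'
#' Per-species relative abundances of the 8-species mock community as
#' recovered by the full-length 16S protocol this simulator emulates.
#'
#' @return named numeric vector of proportions over the eight mock taxa.
#' @export
mock_observed_profile <- function() {
  stats::setNames(
    c(0.200, 0.181, 0.173, 0.139, 0.136, 0.097, 0.049, 0.023),
    mock_taxa)
}
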