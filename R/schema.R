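# Relational schema of the warehouse.
#
# Core table and column names (Protein, ProteinAccessionNumber,
# Protein_has_Taxonomy, TaxonomySynonym, WID, Seq, AccessionNumber, Synonym,
# Taxonomy_WID, Protein_WID) are fixed so that published SQL against this
# family of warehouse schemas runs unmodified; everything else follows the
# Entity / Entity_has_Other naming convention.  Every entity row carries a
# warehouse-wide surrogate identifier (WID) drawn from a single global
# counter, so a WID is unique across all tables of one store.

.wh_schema_tables <- c(
  "WIDSequence",
  "Taxonomy", "TaxonomySynonym",
  "Gene", "GeneSynonym",
  "PTT",
  "Protein", "ProteinAccessionNumber", "ProteinLocusTag",
  "Interaction",
  "UniRefCluster", "UniRefClusterMember",
  "Drug", "DrugTargetAccession",
  "Pathway", "PathwayMemberAccession",
  "Enzyme", "EnzymeName", "EnzymeProteinAccession",
  "OntologyTerm", "OntologyTermParent",
  "Protein_has_Taxonomy", "Protein_has_Gene", "PTT_has_Protein",
  "Drug_has_Protein", "Pathway_has_Protein", "Interaction_has_Protein",
  "Protein_has_UniRefCluster", "Enzyme_has_Protein"
)

#' Emit the warehouse DDL
#'
#' Returns the complete data-definition SQL for the warehouse as a single
#' UTF-8 string.  The DDL is plain standard SQL (no engine-specific clauses),
#' deterministic, and creates the core entity tables, the per-attribute side
#' tables for multi-valued fields, and the `Entity_has_Other` cross-link
#' tables that [resolve_crossrefs()] populates.  Identifier matching in the
#' query layer is made case-insensitive with `UPPER()` joins rather than
#' collation clauses, which keeps the DDL loadable into other relational
#' engines unchanged.
#'
#' @param file Optional path; when given the DDL is also written there.
#' @return The DDL text, invisibly when `file` is given.
#' @examples
#' cat(substr(schema_ddl(), 1, 120))
#' @export
schema_ddl <- function(file = NULL) {
  ddl <- paste0(
"-- bioweave warehouse schema (standard SQL)

CREATE TABLE WIDSequence (
  LastWID INTEGER NOT NULL
);

CREATE TABLE Taxonomy (
  WID INTEGER NOT NULL PRIMARY KEY,
  TaxId INTEGER NOT NULL UNIQUE,
  ParentTaxId INTEGER NOT NULL,
  Rank VARCHAR(64),
  ScientificName VARCHAR(255)
);

CREATE TABLE TaxonomySynonym (
  Taxonomy_WID INTEGER NOT NULL,
  Synonym VARCHAR(255) NOT NULL,
  Position INTEGER NOT NULL
);

CREATE TABLE Gene (
  WID INTEGER NOT NULL PRIMARY KEY,
  GeneId INTEGER NOT NULL UNIQUE,
  LocusTag VARCHAR(64),
  Symbol VARCHAR(64),
  TaxId INTEGER
);

CREATE TABLE GeneSynonym (
  Gene_WID INTEGER NOT NULL,
  Synonym VARCHAR(255) NOT NULL,
  Position INTEGER NOT NULL
);

CREATE TABLE PTT (
  WID INTEGER NOT NULL PRIMARY KEY,
  RepliconAccession VARCHAR(64) NOT NULL,
  StartBp INTEGER NOT NULL,
  EndBp INTEGER NOT NULL,
  Strand CHAR(1),
  Pid VARCHAR(64),
  GeneSymbol VARCHAR(64),
  LocusTag VARCHAR(64),
  Product VARCHAR(255)
);

CREATE TABLE Protein (
  WID INTEGER NOT NULL PRIMARY KEY,
  Name VARCHAR(255),
  Seq TEXT,
  TaxId INTEGER
);

CREATE TABLE ProteinAccessionNumber (
  Protein_WID INTEGER NOT NULL,
  AccessionNumber VARCHAR(64) NOT NULL,
  Position INTEGER NOT NULL
);

CREATE TABLE ProteinLocusTag (
  Protein_WID INTEGER NOT NULL,
  LocusTag VARCHAR(64) NOT NULL,
  Position INTEGER NOT NULL
);

CREATE TABLE Interaction (
  WID INTEGER NOT NULL PRIMARY KEY,
  SourceDataset VARCHAR(64) NOT NULL,
  InteractorA VARCHAR(64) NOT NULL,
  InteractorB VARCHAR(64) NOT NULL,
  DetectionMethod VARCHAR(255),
  PubmedId VARCHAR(32)
);

CREATE TABLE UniRefCluster (
  WID INTEGER NOT NULL PRIMARY KEY,
  ClusterId VARCHAR(64) NOT NULL UNIQUE,
  RepresentativeAccession VARCHAR(64) NOT NULL
);

CREATE TABLE UniRefClusterMember (
  UniRefCluster_WID INTEGER NOT NULL,
  AccessionNumber VARCHAR(64) NOT NULL,
  Position INTEGER NOT NULL
);

CREATE TABLE Drug (
  WID INTEGER NOT NULL PRIMARY KEY,
  DrugBankId VARCHAR(16) NOT NULL UNIQUE,
  Name VARCHAR(255),
  Description TEXT
);

CREATE TABLE DrugTargetAccession (
  Drug_WID INTEGER NOT NULL,
  AccessionNumber VARCHAR(64) NOT NULL,
  Position INTEGER NOT NULL
);

CREATE TABLE Pathway (
  WID INTEGER NOT NULL PRIMARY KEY,
  KeggId VARCHAR(32) NOT NULL UNIQUE,
  Name VARCHAR(255),
  OrganismTaxId INTEGER,
  MapNumber VARCHAR(8)
);

CREATE TABLE PathwayMemberAccession (
  Pathway_WID INTEGER NOT NULL,
  AccessionNumber VARCHAR(64) NOT NULL,
  Position INTEGER NOT NULL
);

CREATE TABLE Enzyme (
  WID INTEGER NOT NULL PRIMARY KEY,
  ECNumber VARCHAR(32) NOT NULL UNIQUE
);

CREATE TABLE EnzymeName (
  Enzyme_WID INTEGER NOT NULL,
  Name VARCHAR(255) NOT NULL,
  Position INTEGER NOT NULL
);

CREATE TABLE EnzymeProteinAccession (
  Enzyme_WID INTEGER NOT NULL,
  AccessionNumber VARCHAR(64) NOT NULL,
  Position INTEGER NOT NULL
);

CREATE TABLE OntologyTerm (
  WID INTEGER NOT NULL PRIMARY KEY,
  TermId VARCHAR(32) NOT NULL UNIQUE,
  Name VARCHAR(255),
  Namespace VARCHAR(64)
);

CREATE TABLE OntologyTermParent (
  OntologyTerm_WID INTEGER NOT NULL,
  ParentTermId VARCHAR(32) NOT NULL,
  Position INTEGER NOT NULL
);

CREATE TABLE Protein_has_Taxonomy (
  Protein_WID INTEGER NOT NULL,
  Taxonomy_WID INTEGER NOT NULL
);

CREATE TABLE Protein_has_Gene (
  Protein_WID INTEGER NOT NULL,
  Gene_WID INTEGER NOT NULL
);

CREATE TABLE PTT_has_Protein (
  PTT_WID INTEGER NOT NULL,
  Protein_WID INTEGER NOT NULL
);

CREATE TABLE Drug_has_Protein (
  Drug_WID INTEGER NOT NULL,
  Protein_WID INTEGER NOT NULL
);

CREATE TABLE Pathway_has_Protein (
  Pathway_WID INTEGER NOT NULL,
  Protein_WID INTEGER NOT NULL
);

CREATE TABLE Interaction_has_Protein (
  Interaction_WID INTEGER NOT NULL,
  Protein_WID INTEGER NOT NULL
);

CREATE TABLE Protein_has_UniRefCluster (
  Protein_WID INTEGER NOT NULL,
  UniRefCluster_WID INTEGER NOT NULL
);

CREATE TABLE Enzyme_has_Protein (
  Enzyme_WID INTEGER NOT NULL,
  Protein_WID INTEGER NOT NULL
);

CREATE INDEX idx_ProteinAccessionNumber_Acc ON ProteinAccessionNumber (AccessionNumber);
CREATE INDEX idx_ProteinAccessionNumber_WID ON ProteinAccessionNumber (Protein_WID);
CREATE INDEX idx_TaxonomySynonym_WID ON TaxonomySynonym (Taxonomy_WID);
CREATE INDEX idx_Protein_has_Taxonomy_P ON Protein_has_Taxonomy (Protein_WID);
CREATE INDEX idx_Protein_has_Taxonomy_T ON Protein_has_Taxonomy (Taxonomy_WID);
CREATE INDEX idx_Drug_has_Protein_D ON Drug_has_Protein (Drug_WID);
CREATE INDEX idx_Pathway_has_Protein_P ON Pathway_has_Protein (Pathway_WID);
CREATE INDEX idx_PTT_Replicon ON PTT (RepliconAccession);
CREATE INDEX idx_Gene_LocusTag ON Gene (LocusTag);
")
  if (!is.null(file)) {
    cat(ddl, file = file)
    return(invisible(ddl))
  }
  ddl
}

# Split the DDL into individual statements executable one at a time.
wh_ddl_statements <- function() {
  ddl <- schema_ddl()
  ddl <- gsub("--[^\n]*", "", ddl)
  stmts <- strsplit(ddl, ";", fixed = TRUE)[[1]]
  stmts <- trimws(stmts)
  stmts[nzchar(stmts)]
}
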