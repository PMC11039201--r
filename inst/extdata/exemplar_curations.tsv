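gene	gene_id	disease	disease_id	allelic_requirement	qualifiers	disease_associated_consequences	known_pathogenic_variant_classes	mechanism_note	source
MYH7	HGNC:7577	Hypertrophic cardiomyopathy		monoallelic_autosomal	HP:0003831;HP:0003829	altered gene product sequence	missense_variant	Abnormal gene product required; gene is not haploinsufficient (PTCs not pathogenic)	curated example
KCNQ1	HGNC:6294	Short QT syndrome		monoallelic_autosomal		altered gene product sequence	missense_variant	Single recurrent gain-of-function missense NP_000209.2:p.(Val141Met); GoF evidence does not generalize to other missense or to LOF	curated example
KCNQ1	HGNC:6294	Long QT syndrome		monoallelic_autosomal	HP:0003829	altered gene product sequence;decreased gene product level	missense_variant;stop_gained|NMD_triggering	Reportable secondary finding in cardiovascular screening	curated example
FBN1	HGNC:3603	Marfan syndrome		monoallelic_autosomal	HP:0034857	altered gene product sequence;decreased gene product level	missense_variant;stop_gained|NMD_triggering;splice_donor_variant		curated example
EFNB1	HGNC:3226	Craniofrontonasal dysplasia		monoallelic_X_heterozygous	HP:0034343	altered gene product sequence;decreased gene product level	missense_variant;stop_gained|NMD_triggering;frameshift_variant|NMD_triggering	Cellular interference in the mosaic state; hemizygous males mildly affected	curated example
DMPK	HGNC:2933	Myotonic dystrophy type 1		monoallelic_autosomal	HP:0003743	altered gene product level		CTG triplet repeat expansion	curated example
DHH	HGNC:2865	46,XY gonadal dysgenesis		biallelic_autosomal	HP:0001475	decreased gene product level;absent gene product	missense_variant;stop_gained|NMD_triggering	Manifests only in XY males; XX females phenotypically normal	curated example
NF1	HGNC:7765	Neurofibromatosis type 1		monoallelic_autosomal	HP:0034950	decreased gene product level;absent gene product	stop_gained|NMD_triggering;frameshift_variant|NMD_triggering;splice_donor_variant;missense_variant	Penetrance close to 100%	curated example
CYP1B1	HGNC:2597	Primary congenital glaucoma		biallelic_autosomal	HP:4000158	decreased gene product level;absent gene product;altered gene product sequence	missense_variant;stop_gained|NMD_triggering	Approximately 90% penetrance	curated example
IRF6	HGNC:6121	Van der Woude syndrome		monoallelic_autosomal	HP:4000158	decreased gene product level;altered gene product sequence	missense_variant;stop_gained|NMD_triggering	Cleft lip and/or palate; penetrance estimated at 80%	curated example
C9orf72	HGNC:28337	Frontotemporal dementia and/or amyotrophic lateral sclerosis		monoallelic_autosomal	HP:4000159;HP:0003831	altered gene product level		Hexanucleotide repeat expansion; approximately 50% penetrance	curated example
RYR1	HGNC:10483	Malignant hyperthermia		monoallelic_autosomal	HP:0003829	altered gene product sequence	missense_variant	Mechanism (dominant negative vs haploinsufficiency) unresolved	curated example
CACNA1S	HGNC:1397	Malignant hyperthermia		monoallelic_autosomal	HP:0003829	altered gene product sequence	missense_variant	Mechanism unresolved	curated example
GENEX		Congenital heart disease (toy X-linked recessive)		monoallelic_X_hemizygous		decreased gene product level;absent gene product	stop_gained|NMD_triggering;frameshift_variant|NMD_triggering	Hypothetical X-linked dual-phenotype gene; hemizygous or biallelic variation	synthetic
GENEX		Late-onset cardiomyopathy (toy X-linked dominant)		monoallelic_X_heterozygous	HP:0003831	decreased gene product level;absent gene product;altered gene product sequence	missense_variant;stop_gained|NMD_triggering	Hypothetical X-linked dual-phenotype gene; heterozygous monoallelic variation	synthetic
TOYY1		Y-linked spermatogenic failure (toy)		monoallelic_Y_hemizygous		decreased gene product level;absent gene product	stop_gained|NMD_triggering		synthetic
MT-TOY1		Mitochondrial myopathy (toy)		mitochondrial		altered gene product sequence	missense_variant	Heteroplasmy fraction recorded when available	synthetic
SHOX	HGNC:10853	Leri-Weill dyschondrosteosis (toy PAR curation)		monoallelic_PAR		decreased gene product level;absent gene product;altered gene product sequence	missense_variant;stop_gained|NMD_triggering	Pseudoautosomal region 1 gene	synthetic
SHOX	HGNC:10853	Langer mesomelic dysplasia (toy PAR curation)		biallelic_PAR		absent gene product;decreased gene product level	stop_gained|NMD_triggering	Pseudoautosomal region 1 gene	synthetic
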