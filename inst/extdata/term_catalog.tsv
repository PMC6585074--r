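key	prefix	iri	label	ontology	family	scheme
iao-document	iao	http://purl.obolibrary.org/obo/IAO_0000310	document	IAO
abstract	iao	http://purl.obolibrary.org/obo/IAO_0000315	abstract	IAO	section
author-list	iao	http://purl.obolibrary.org/obo/IAO_0000321	author list	IAO	section
introduction	iao	http://purl.obolibrary.org/obo/IAO_0000316	introduction	IAO	section
methods-section	iao	http://purl.obolibrary.org/obo/IAO_0000317	methods section	IAO	section
results-section	iao	http://purl.obolibrary.org/obo/IAO_0000318	results section	IAO	section
discussion-section	iao	http://purl.obolibrary.org/obo/IAO_0000319	discussion section	IAO	section
conclusion-section	iao	http://purl.obolibrary.org/obo/IAO_0000615	conclusion section	IAO	section
references-section	iao	http://purl.obolibrary.org/obo/IAO_0000320	references section	IAO	section
document	ngo	https://w3id.org/anatomygraphs/ngo/document-named-graph	document named graph	local		document
assertions	ngo	https://w3id.org/anatomygraphs/ngo/assertions-named-graph	assertions named graph	local		assertions
parthood	ngo	https://w3id.org/anatomygraphs/ngo/parthood-named-graph	parthood named graph	local		parthood
anatomical-surface-texture	ngo	https://w3id.org/anatomygraphs/ngo/anatomical-surface-texture-named-graph	anatomical surface texture named graph	local	texture	quality
anatomical-structure-volume	ngo	https://w3id.org/anatomygraphs/ngo/anatomical-structure-volume-named-graph	anatomical structure volume named graph	local	volume	measurement
anatomical-structure-length	ngo	https://w3id.org/anatomygraphs/ngo/anatomical-structure-length-named-graph	anatomical structure length named graph	local	length	measurement
assay-data	ngo	https://w3id.org/anatomygraphs/ngo/assay-data-named-graph	assay data named graph	local		assay-data
specimen-collection	ngo	https://w3id.org/anatomygraphs/ngo/specimen-collection-named-graph	specimen collection named graph	local		specimen-collection
specimen-history	ngo	https://w3id.org/anatomygraphs/ngo/specimen-history-named-graph	specimen history named graph	local		specimen-history
unclassified	ngo	https://w3id.org/anatomygraphs/ngo/unclassified-named-graph	unclassified named graph	local		unclassified
instance-anatomy	akg	https://w3id.org/anatomygraphs/class/instance-anatomy	instance anatomy	local
microscopy-assay	akg	https://w3id.org/anatomygraphs/class/microscopy-assay	microscopy assay	IAO (as cited)
person	akg	https://w3id.org/anatomygraphs/class/person	person	local
geographic-place	akg	https://w3id.org/anatomygraphs/class/geographic-place	geographic place	local
live-trap	akg	https://w3id.org/anatomygraphs/class/live-trap	live trap	local
assay	obi	http://purl.obolibrary.org/obo/OBI_0000070	assay	OBI
specimen-collection-process	obi	http://purl.obolibrary.org/obo/OBI_0000659	specimen collection process	OBI
material-processing	obi	http://purl.obolibrary.org/obo/OBI_0000094	material processing	OBI
specimen	obi	http://purl.obolibrary.org/obo/OBI_0100051	specimen	OBI
protocol	obi	http://purl.obolibrary.org/obo/OBI_0000272	protocol	OBI
device	obi	http://purl.obolibrary.org/obo/OBI_0000968	device	OBI
material-entity	bfo	http://purl.obolibrary.org/obo/BFO_0000040	material entity	BFO
texture	pato	http://purl.obolibrary.org/obo/PATO_0000150	texture	PATO	texture
rough	pato	http://purl.obolibrary.org/obo/PATO_0000700	rough	PATO	texture
smooth	pato	http://purl.obolibrary.org/obo/PATO_0000701	smooth	PATO	texture
volume	pato	http://purl.obolibrary.org/obo/PATO_0000918	volume	PATO	volume
length	pato	http://purl.obolibrary.org/obo/PATO_0000122	length	PATO	length
meter	uo	http://purl.obolibrary.org/obo/UO_0000008	meter	UO	metre-unit
centimeter	uo	http://purl.obolibrary.org/obo/UO_0000015	centimeter	UO	metre-unit
millimeter	uo	http://purl.obolibrary.org/obo/UO_0000016	millimeter	UO	metre-unit
micrometer	uo	http://purl.obolibrary.org/obo/UO_0000017	micrometer	UO	metre-unit
milliliter	uo	http://purl.obolibrary.org/obo/UO_0000098	milliliter	UO	volume-unit
head	hao	http://purl.obolibrary.org/obo/HAO_0000397	head	HAO	part
organism	uberon	http://purl.obolibrary.org/obo/UBERON_0000468	multicellular organism	UBERON	part
uberon-head	uberon	http://purl.obolibrary.org/obo/UBERON_0000033	head	UBERON	part
thorax	uberon	http://purl.obolibrary.org/obo/UBERON_0000915	thorax	UBERON	part
abdomen	uberon	http://purl.obolibrary.org/obo/UBERON_0000916	abdomen	UBERON	part
eye	uberon	http://purl.obolibrary.org/obo/UBERON_0000970	eye	UBERON	part
mouth	uberon	http://purl.obolibrary.org/obo/UBERON_0000165	mouth	UBERON	part
wing	uberon	http://purl.obolibrary.org/obo/UBERON_0000023	wing	UBERON	part
leg	uberon	http://purl.obolibrary.org/obo/UBERON_0000978	leg	UBERON	part
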