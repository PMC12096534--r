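# Most recent references co-mentioning a compound and a disease.
PREFIX vocab: <http://rdf.ncbi.nlm.nih.gov/pubchem/vocabulary#>
PREFIX dcterms: <http://purl.org/dc/terms/>
PREFIX prism: <http://prismstandard.org/namespaces/basic/3.0/>
PREFIX compound: <http://rdf.ncbi.nlm.nih.gov/pubchem/compound/>
PREFIX disease: <http://rdf.ncbi.nlm.nih.gov/pubchem/disease/>
SELECT ?ref ?date ?journal ?title
WHERE {
  ?ref vocab:discussesAsDerivedByTextMining compound:CID{{cid}} .
  ?ref vocab:discussesAsDerivedByTextMining disease:DZID{{dzid}} .
  ?ref dcterms:title ?title .
  ?ref dcterms:date ?date .
  ?ref dcterms:isPartOf ?j .
  ?j prism:publicationName ?journal .
}
ORDER BY DESC(?date) DESC(STR(?ref))
LIMIT {{limit}}
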