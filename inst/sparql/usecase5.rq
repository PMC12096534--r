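# Human genes co-mentioned with two diseases, by score sum.
PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX sio: <http://semanticscience.org/resource/>
PREFIX bao: <http://www.bioassayontology.org/bao#>
PREFIX up: <http://purl.uniprot.org/core/>
PREFIX skos: <http://www.w3.org/2004/02/skos/core#>
PREFIX disease: <http://rdf.ncbi.nlm.nih.gov/pubchem/disease/>
PREFIX taxonomy: <http://rdf.ncbi.nlm.nih.gov/pubchem/taxonomy/>
SELECT ?gene ?name ?s1 ?s2
WHERE {
  {
    SELECT ?gene ?s1
    WHERE {
      ?gd1 rdf:type sio:SIO_000983 ;
           rdf:subject disease:DZID{{d1}} ;
           rdf:object ?gene ;
           sio:SIO_000300 ?s1 .
    }
    ORDER BY DESC(?s1) ASC(STR(?gene))
    LIMIT {{inner_limit}}
  }
  ?gd2 rdf:type sio:SIO_000983 ;
       rdf:subject disease:DZID{{d2}} ;
       rdf:object ?gene ;
       sio:SIO_000300 ?s2 .
  ?gid bao:BAO_0002870 ?gene ;
       up:organism taxonomy:TAXID{{taxon}} ;
       skos:prefLabel ?name .
}
ORDER BY DESC(?s1 + ?s2) ASC(STR(?gene))
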