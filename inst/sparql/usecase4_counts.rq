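# Number of references simultaneously mentioning a drug and three genes.
PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX sio: <http://semanticscience.org/resource/>
PREFIX obo: <http://purl.obolibrary.org/obo/>
PREFIX vocab: <http://rdf.ncbi.nlm.nih.gov/pubchem/vocabulary#>
PREFIX gene: <http://rdf.ncbi.nlm.nih.gov/pubchem/gene/>
SELECT ?compound (COUNT(DISTINCT ?ref) AS ?nrefs)
WHERE {
  {
    SELECT DISTINCT ?compound
    WHERE {
      ?c1 rdf:type sio:SIO_001257 ;
          rdf:subject gene:{{g1}} ;
          rdf:object ?compound .
      ?c2 rdf:type sio:SIO_001257 ;
          rdf:subject gene:{{g2}} ;
          rdf:object ?compound .
      ?c3 rdf:type sio:SIO_001257 ;
          rdf:subject gene:{{g3}} ;
          rdf:object ?compound .
      ?compound obo:RO_0000087 vocab:{{role}} .
    }
  }
  ?ref vocab:discussesAsDerivedByTextMining ?compound ,
       gene:{{g1}} , gene:{{g2}} , gene:{{g3}} .
}
GROUP BY ?compound
ORDER BY DESC(?nrefs) ASC(STR(?compound))
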