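# FDA-approved drugs co-mentioned with three genes, by score sum.
PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX sio: <http://semanticscience.org/resource/>
PREFIX obo: <http://purl.obolibrary.org/obo/>
PREFIX vocab: <http://rdf.ncbi.nlm.nih.gov/pubchem/vocabulary#>
PREFIX gene: <http://rdf.ncbi.nlm.nih.gov/pubchem/gene/>
SELECT ?compound ?s1 ?s2 ?s3
WHERE {
  ?c1 rdf:type sio:SIO_001257 ;
      rdf:subject gene:{{g1}} ;
      rdf:object ?compound ;
      sio:SIO_000300 ?s1 .
  ?c2 rdf:type sio:SIO_001257 ;
      rdf:subject gene:{{g2}} ;
      rdf:object ?compound ;
      sio:SIO_000300 ?s2 .
  ?c3 rdf:type sio:SIO_001257 ;
      rdf:subject gene:{{g3}} ;
      rdf:object ?compound ;
      sio:SIO_000300 ?s3 .
  ?compound obo:RO_0000087 vocab:{{role}} .
}
ORDER BY DESC(?s1 + ?s2 + ?s3) ASC(STR(?compound))
LIMIT {{limit}}
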