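# Synthetic stand-in for the narrow scope of the hepatic-disorders
# Standardised MedDRA Query (SMQ 20000007). MedDRA is licensed, so this file
# lists plausible hepatic-injury Preferred Terms for testing and synthetic
# data only; it is NOT the authoritative 144-term narrow list. Licence
# holders should replace this file (one PT per line, "#" comments) with the
# official narrow-scope export and point load_smq_terms() at it.
Acute hepatic failure
Ascites
Autoimmune hepatitis
Bilirubin conjugated increased
Blood bilirubin increased
Cholestasis
Cholestatic liver injury
Coma hepatic
Drug-induced liver injury
Hepatic atrophy
Hepatic cirrhosis
Hepatic cytolysis
Hepatic encephalopathy
Hepatic enzyme increased
Hepatic failure
Hepatic fibrosis
Hepatic function abnormal
Hepatic infiltration eosinophilic
Hepatic necrosis
Hepatic steatosis
Hepatitis
Hepatitis acute
Hepatitis cholestatic
Hepatitis fulminant
Hepatitis toxic
Hepatobiliary disease
Hepatocellular injury
Hepatomegaly
Hepatorenal failure
Hepatorenal syndrome
Hepatotoxicity
Hyperbilirubinaemia
Hypertransaminasaemia
Icterus
Jaundice
Jaundice cholestatic
Liver disorder
Liver function test abnormal
Liver function test increased
Liver injury
Liver transplant
Mixed liver injury
Ocular icterus
Portal hypertension
Subacute hepatic failure
Transaminases increased
Yellow skin
Alanine aminotransferase increased
Aspartate aminotransferase increased
Gamma-glutamyltransferase increased
Blood alkaline phosphatase increased
Hepatic lesion
Hepatic haemorrhage
Cholestasis of pregnancy
Biliary cirrhosis
Nodular regenerative hyperplasia
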