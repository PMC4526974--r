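canonical	intent	mesh	aliases
Affiliation	navigational	FALSE	ad,affiliation,affl
All Fields	informational	FALSE	all,all fields
Author	navigational	FALSE	au,author,author name,au name,auth
Author Identifier	navigational	FALSE	auid,author id
Book	navigational	FALSE	book
Completion Date	navigational	FALSE	dcom,completion date
Conflict of Interest Statement	informational	FALSE	cois
Corporate Author	navigational	FALSE	cn,corporate author
Create Date	navigational	FALSE	crdt,create date
EC/RN Number	informational	FALSE	rn,ec number,rn number
Editor	navigational	FALSE	ed,editor
Entry Date	navigational	FALSE	edat,entrez date,entry date
Filter	informational	FALSE	filter,fltr
First Author Name	navigational	FALSE	1au,first author
Full Author Name	navigational	FALSE	fau,full author name,full author
Full Investigator Name	navigational	FALSE	fir,full investigator name
Grant Number	navigational	FALSE	gr,grant number
Investigator	navigational	FALSE	ir,investigator
ISBN	navigational	FALSE	isbn
Issue	navigational	FALSE	ip,issue,iss
Journal	navigational	FALSE	ta,journal,jour,journal name,jrnl
Language	informational	FALSE	la,lang,language
Last Author Name	navigational	FALSE	lastau,last author
Location ID	navigational	FALSE	lid,location id
MeSH Date	navigational	FALSE	mhda,mesh date
MeSH Major Topic	informational	TRUE	majr,mj,mesh major topic,major
MeSH Subheading	informational	TRUE	sh,subheading,mesh subheading,subh
MeSH Terms	informational	TRUE	mh,mesh,mesh terms,mesh term,msh
Modification Date	navigational	FALSE	lr,modification date
NLM Unique ID	navigational	FALSE	jid,nlm unique id
Other Term	informational	FALSE	ot,other term,keyword,kw
Owner	navigational	FALSE	own,owner
Pagination	navigational	FALSE	pg,page,pages,pagination
Personal Name as Subject	informational	FALSE	ps,personal name as subject
Pharmacological Action	informational	FALSE	pa,pharmacological action
Place of Publication	navigational	FALSE	pl,place of publication
PMID	navigational	FALSE	pmid,uid
Publication Date	navigational	FALSE	dp,pdat,publication date,pub date
Publication Type	informational	FALSE	pt,ptyp,publication type,pub type
Publisher	navigational	FALSE	pubn,publisher
Secondary Source ID	navigational	FALSE	si,secondary source id
Subset	informational	FALSE	sb,subset
Supplementary Concept	informational	TRUE	nm,substance name,supplementary concept
Text Words	informational	FALSE	tw,text word,text words,word
Title	informational	FALSE	ti,title
Title/Abstract	informational	FALSE	tiab,title abstract,title/abstract,ti ab
Transliterated Title	navigational	FALSE	tt,transliterated title
Volume	navigational	FALSE	vi,volume,vol
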