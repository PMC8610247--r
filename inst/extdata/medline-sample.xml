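<?xml version="1.0" encoding="UTF-8"?>
<PubmedArticleSet>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>1001</PMID>
      <Article>
        <Journal>
          <ISSN>1234-5678</ISSN>
          <JournalIssue>
            <PubDate><Year>2018</Year></PubDate>
          </JournalIssue>
          <Title>Journal of Worked Examples</Title>
        </Journal>
        <ArticleTitle>A two-author research article with full history</ArticleTitle>
        <Abstract>
          <AbstractText>A short abstract.</AbstractText>
        </Abstract>
        <AuthorList>
          <Author>
            <LastName>Doe</LastName>
            <ForeName>Jane</ForeName>
            <Initials>J</Initials>
          </Author>
          <Author>
            <LastName>Roe</LastName>
            <ForeName>Richard</ForeName>
            <Initials>R</Initials>
          </Author>
        </AuthorList>
        <PublicationTypeList>
          <PublicationType>Journal Article</PublicationType>
        </PublicationTypeList>
      </Article>
      <MedlineJournalInfo>
        <MedlineTA>J Worked Ex</MedlineTA>
        <NlmUniqueID>100000001</NlmUniqueID>
      </MedlineJournalInfo>
    </MedlineCitation>
    <PubmedData>
      <History>
        <PubMedPubDate PubStatus="received">
          <Year>2018</Year><Month>1</Month><Day>1</Day>
        </PubMedPubDate>
        <PubMedPubDate PubStatus="accepted">
          <Year>2018</Year><Month>2</Month><Day>1</Day>
        </PubMedPubDate>
        <PubMedPubDate PubStatus="pubmed">
          <Year>2018</Year><Month>3</Month><Day>1</Day>
        </PubMedPubDate>
      </History>
    </PubmedData>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>1002</PMID>
      <Article>
        <Journal>
          <ISSN>1234-5678</ISSN>
          <JournalIssue>
            <PubDate><Year>2016</Year></PubDate>
          </JournalIssue>
          <Title>Journal of Worked Examples</Title>
        </Journal>
        <ArticleTitle>An authorless editorial without an abstract</ArticleTitle>
        <PublicationTypeList>
          <PublicationType>Editorial</PublicationType>
        </PublicationTypeList>
      </Article>
      <MedlineJournalInfo>
        <MedlineTA>J Worked Ex</MedlineTA>
        <NlmUniqueID>100000001</NlmUniqueID>
      </MedlineJournalInfo>
    </MedlineCitation>
    <PubmedData>
      <History/>
    </PubmedData>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>1003</PMID>
      <Article>
        <Journal>
          <ISSN>8765-4321</ISSN>
          <JournalIssue>
            <PubDate><MedlineDate>2019 Jan-Feb</MedlineDate></PubDate>
          </JournalIssue>
          <Title>Annals of Group Authorship</Title>
        </Journal>
        <ArticleTitle>A collective-author article dated by MedlineDate</ArticleTitle>
        <Abstract>
          <AbstractText>Another abstract.</AbstractText>
        </Abstract>
        <AuthorList>
          <Author>
            <CollectiveName>Red</CollectiveName>
          </Author>
        </AuthorList>
        <PublicationTypeList>
          <PublicationType>Journal Article</PublicationType>
        </PublicationTypeList>
      </Article>
      <MedlineJournalInfo>
        <MedlineTA>Ann Group Auth</MedlineTA>
        <NlmUniqueID>100000002</NlmUniqueID>
      </MedlineJournalInfo>
    </MedlineCitation>
    <PubmedData>
      <History>
        <PubMedPubDate PubStatus="accepted">
          <Year>2018</Year><Month>12</Month><Day>15</Day>
        </PubMedPubDate>
      </History>
    </PubmedData>
  </PubmedArticle>
</PubmedArticleSet>
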